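# Sequence-level statistics: per-frame metric trajectories, first-vs-last
# paired deltas, correlation against a classifier-confidence series, and
# distribution summaries.

.TRAJECTORY_METRICS <- c("asymmetry", "border_gradient", "convexity",
                         "color_dispersion", "diameter")

#' Compute per-frame metric trajectories for a sequence
#'
#' Evaluates the per-frame metric vector for every frame and adds the color
#' evolution of each frame relative to frame 0 (matched-cluster centroid
#' distance; 0 for the first frame). Per-frame color segmentations are
#' computed once and reused for both the dispersion and the evolution
#' columns. Deterministic for a fixed seed.
#'
#' @param seq A \linkS4class{FrameSequence} with at least 2 frames.
#' @param seed Integer seed controlling the color clustering.
#' @return Data frame with one row per frame: \code{frame_index} (0-based),
#'   the five per-frame metrics, \code{diameter_units} and
#'   \code{color_evolution_from_first}.
#' @export
computeTrajectories <- function(seq, seed = 17L) {
  n <- length(seq)
  if (n < 2L) stop("at least 2 frames required")
  segs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- seq[[i]]
    res <- tryCatch({
      segs[[i]] <- colorSegment(frameImage(fr), frameMask(fr), seed = seed)
      .metricRow(fr, segs[[i]])
    }, error = function(e) stop("frame ", i - 1L, ": ", conditionMessage(e)))
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  out$frame_index <- seq_len(n) - 1L
  out$color_evolution_from_first <- vapply(seq_len(n), function(i) {
    if (i == 1L) 0 else colorEvolutionScore(segs[[1]], segs[[i]])
  }, numeric(1))
  out[, c("frame_index", .TRAJECTORY_METRICS, "diameter_units",
          "color_evolution_from_first")]
}

#' First-versus-last relative change of each metric
#'
#' For each metric trajectory, the relative change in percent between the
#' last and the first frame, \code{100 (last - first) / first}; positive =
#' increase. When the first-frame value is below \code{eps} (1e-6) the
#' absolute difference is reported instead and flagged in the \code{type}
#' column.
#'
#' @param traj Data frame from \code{\link{computeTrajectories}}.
#' @param eps Threshold below which first-frame values are treated as zero.
#' @return Data frame with columns \code{metric}, \code{first}, \code{last},
#'   \code{delta} and \code{type} (\code{"relative_pct"} or
#'   \code{"absolute"}).
#' @export
firstLastDelta <- function(traj, eps = 1e-6) {
  metrics <- intersect(c(.TRAJECTORY_METRICS, "color_evolution_from_first"),
                       names(traj))
  res <- lapply(metrics, function(m) {
    v <- traj[[m]]
    first <- v[1]; last <- v[length(v)]
    if (abs(first) > eps) {
      data.frame(metric = m, first = first, last = last,
                 delta = 100 * (last - first) / first,
                 type = "relative_pct", stringsAsFactors = FALSE)
    } else {
      data.frame(metric = m, first = first, last = last,
                 delta = last - first, type = "absolute",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Pearson correlation of metric trajectories with a confidence series
#'
#' Correlates each metric trajectory with a per-frame classifier-confidence
#' series (e.g. the confidence of a nevus diagnosis) using the
#' product-moment correlation; two-sided p-values come from the
#' t-distribution with n - 2 degrees of freedom. Constant series make the
#' correlation undefined: \code{NA} is reported rather than 0. Raw p-values
#' are reported by default; Benjamini-Hochberg adjustment is available via
#' \code{pAdjust = "BH"}.
#'
#' @param traj Data frame from \code{\link{computeTrajectories}}.
#' @param conf Numeric confidence vector, one value in \code{[0, 1]} per
#'   frame.
#' @param pAdjust \code{"none"} (default) or \code{"BH"}.
#' @return Data frame with columns \code{metric}, \code{rho},
#'   \code{p_value} and \code{n}.
#' @importFrom stats cor.test sd p.adjust
#' @export
correlateWithConfidence <- function(traj, conf, pAdjust = c("none", "BH")) {
  pAdjust <- match.arg(pAdjust)
  if (length(conf) != nrow(traj))
    stop("confidence series length (", length(conf),
         ") must equal the number of frames (", nrow(traj), ")")
  if (nrow(traj) < 3L) stop("at least 3 frames required for correlation")
  metrics <- intersect(c(.TRAJECTORY_METRICS, "color_evolution_from_first"),
                       names(traj))
  res <- lapply(metrics, function(m) {
    v <- traj[[m]]
    if (stats::sd(v) < 1e-12 || stats::sd(conf) < 1e-12) {
      data.frame(metric = m, rho = NA_real_, p_value = NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(v, conf, method = "pearson")
      data.frame(metric = m, rho = unname(ct$estimate),
                 p_value = ct$p.value, n = length(v),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (pAdjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Distribution summary of each metric trajectory
#'
#' Five-number summary (min, first quartile, median, third quartile, max)
#' plus the interquartile range, per metric, over all frames. Quantiles use
#' linear interpolation (type 7), the convention most boxplot
#' implementations default to.
#'
#' @param traj Data frame from \code{\link{computeTrajectories}}.
#' @return Data frame with columns \code{metric}, \code{min}, \code{q1},
#'   \code{median}, \code{q3}, \code{max} and \code{iqr}.
#' @importFrom stats quantile
#' @export
distributionSummary <- function(traj) {
  metrics <- intersect(c(.TRAJECTORY_METRICS, "color_evolution_from_first"),
                       names(traj))
  res <- lapply(metrics, function(m) {
    q <- stats::quantile(traj[[m]], c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    data.frame(metric = m, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], iqr = q[4] - q[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
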