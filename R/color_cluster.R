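# Color clustering of lesion pixels in linear RGB, with unimodality gating,
# and the two color metrics built on it (within-cluster dispersion and
# between-segmentation evolution).

# Deterministic subsample: evenly spaced elements of a vector/matrix rows.
.evenSubsample <- function(n, m) {
  if (n <= m) seq_len(n) else unique(round(seq(1, n, length.out = m)))
}

# Dequantize a sorted vector for the dip test: colors inherited from 8-bit
# images sit on a discrete grid, and the resulting atoms would read as
# spurious modes. Each run of tied values is spread evenly over the interval
# between the midpoints to its neighboring distinct values (deterministic,
# monotone; exact for rounded continuous data).
.spreadTies <- function(xs) {
  ux <- unique(xs)
  m <- length(ux)
  if (m == length(xs) || m < 2L) return(xs)
  cnt <- tabulate(match(xs, ux))
  lo <- c(ux[1], (ux[-1] + ux[-m]) / 2)
  hi <- c((ux[-1] + ux[-m]) / 2, ux[m])
  unlist(lapply(seq_len(m), function(j) {
    if (cnt[j] == 1L) ux[j]
    else lo[j] + (seq_len(cnt[j]) - 0.5) / cnt[j] * (hi[j] - lo[j])
  }), use.names = FALSE)
}

#' Cluster lesion colors in linear RGB
#'
#' Lesion pixels are converted from sRGB to linear RGB (unit cube). The
#' color distribution is first tested for unimodality with Hartigan's dip
#' test applied to the projection of the colors onto their first principal
#' direction; if the test does not reject (p >= \code{alpha}) the lesion is
#' treated as single-colored (k = 1, centroid = mean color). Otherwise the
#' cluster count k in \code{2..kMax} is chosen by the best mean silhouette
#' coefficient of a k-means partition (Euclidean, evaluated on a
#' deterministic subsample of at most 2000 pixels; k-means with 10 restarts
#' under the given seed), and all lesion pixels are labeled with the chosen
#' partition.
#'
#' @param image \code{H x W x 3} sRGB array in \code{[0, 255]}.
#' @param mask Logical lesion mask (largest component used); at least 50
#'   lesion pixels are required.
#' @param kMax Largest cluster count searched (default 6).
#' @param alpha Dip-test significance level gating multimodality
#'   (default 0.05).
#' @param seed Integer seed for the k-means restarts.
#' @return A \linkS4class{ColorSegmentation}.
#' @examples
#' fr <- generateLesion(lesionSpec(seed = 4))
#' seg <- colorSegment(frameImage(fr), frameMask(fr), seed = 1)
#' nClusters(seg)
#' @importFrom stats kmeans prcomp
#' @importFrom cluster silhouette
#' @export
colorSegment <- function(image, mask, kMax = 6L, alpha = 0.05, seed = 17L) {
  mask <- .largestComponent(mask)
  pixIdx <- which(mask)
  n <- length(pixIdx)
  if (n < 50L) stop("fewer than 50 lesion pixels (", n, ")")
  d <- dim(image)
  cols <- cbind(image[pixIdx], image[pixIdx + d[1] * d[2]],
                image[pixIdx + 2L * d[1] * d[2]])
  # dequantize 8-bit intensities (uniform +/- half a level, seeded) so that
  # the quantization lattice cannot read as spurious color modes
  cols <- cols + matrix(.withSeed(seed, stats::runif(3L * n, -0.5, 0.5)),
                        n, 3L)
  lin <- srgbToLinear(.clamp(cols, 0, 255))

  # unimodality gate: dip test on the first-principal-direction projection,
  # evaluated on at most 2000 evenly spaced order statistics (deterministic;
  # same budget as the silhouette search)
  pc1 <- stats::prcomp(lin, center = TRUE, scale. = FALSE)$x[, 1]
  proj <- .spreadTies(sort(pc1))[.evenSubsample(n, 2000L)]
  dipP <- dipUnimodalityTest(proj)$p.value

  if (dipP >= alpha) {
    k <- 1L
    labels <- rep(1L, n)
    centroids <- matrix(colMeans(lin), 1, 3)
  } else {
    sub <- lin[.evenSubsample(n, 2000L), , drop = FALSE]
    dd <- stats::dist(sub)
    best <- NULL
    for (k in 2:kMax) {
      fit <- .withSeed(seed + k, stats::kmeans(sub, centers = k, nstart = 10,
                                               iter.max = 100))
      sil <- mean(cluster::silhouette(fit$cluster, dd)[, 3])
      if (is.null(best) || sil > best$sil) best <- list(k = k, fit = fit,
                                                        sil = sil)
    }
    k <- best$k
    # label every lesion pixel: Lloyd refinement from the subsample centers,
    # falling back to plain nearest-centroid assignment if a cluster empties
    full <- tryCatch(
      .withSeed(seed, stats::kmeans(lin, centers = best$fit$centers,
                                    iter.max = 100)),
      error = function(e) NULL)
    if (is.null(full)) {
      d2 <- vapply(seq_len(k), function(c)
        colSums((t(lin) - best$fit$centers[c, ])^2), numeric(n))
      labels <- max.col(-d2)
      centroids <- t(vapply(seq_len(k), function(c)
        colMeans(lin[labels == c, , drop = FALSE]), numeric(3)))
    } else {
      labels <- as.integer(full$cluster)
      centroids <- full$centers
    }
  }
  weights <- as.numeric(tabulate(labels, k)) / n
  masks <- lapply(seq_len(k), function(c) {
    m <- matrix(FALSE, d[1], d[2])
    m[pixIdx[labels == c]] <- TRUE
    m
  })
  new("ColorSegmentation", labels = labels, pixelIndex = as.integer(pixIdx),
      centroids = unname(centroids), weights = weights, clusterMasks = masks,
      canvasDim = d[1:2])
}

# Normalizers: half and full main diagonal of the linear-RGB unit cube.
.DISPERSION_NORM <- sqrt(3) / 2
.EVOLUTION_NORM <- sqrt(3)

#' Within-cluster color dispersion score
#'
#' For each color cluster, the standard deviation of the Euclidean distances
#' of its pixels (linear RGB) to the cluster centroid, normalized by half
#' the unit-cube main diagonal (\code{sqrt(3)/2}); the score is the
#' cluster-weight weighted sum, clamped to \code{[0, 1]}. 0 means each
#' cluster is perfectly uniform in color; large values mean strong color
#' variegation within clusters.
#'
#' @param image \code{H x W x 3} sRGB array in \code{[0, 255]}.
#' @param mask Logical lesion mask (must match the segmentation).
#' @param seg \linkS4class{ColorSegmentation} computed from this image/mask.
#' @return Scalar in \code{[0, 1]}.
#' @export
colorDispersionScore <- function(image, mask, seg) {
  d <- dim(image)
  idx <- seg@pixelIndex
  lin <- srgbToLinear(cbind(image[idx], image[idx + d[1] * d[2]],
                            image[idx + 2L * d[1] * d[2]]))
  k <- nClusters(seg)
  sds <- vapply(seq_len(k), function(c) {
    sel <- seg@labels == c
    if (sum(sel) < 2L) return(0)
    dist <- sqrt(rowSums((lin[sel, , drop = FALSE] -
                          matrix(seg@centroids[c, ], sum(sel), 3,
                                 byrow = TRUE))^2))
    stats::sd(dist)
  }, numeric(1))
  .clamp(sum(seg@weights * sds / .DISPERSION_NORM), 0, 1)
}

#' Color evolution score between two segmentations
#'
#' Quantifies the color change of a lesion between two time points. Clusters
#' of the segmentation with fewer (or equal) clusters are matched to
#' clusters of the other by greedy maximum mask-IoU correspondence (each
#' cluster matched at most once; ties broken toward lower cluster indices).
#' The Euclidean distances between matched centroids (linear RGB) are
#' averaged, normalized by the maximal possible distance \code{sqrt(3)}, and
#' scaled by \code{m / max(kA, kB)} where m is the number of matched pairs,
#' so unmatched clusters neither inflate nor escape the \code{[0, 1]} range.
#' 0 means identical cluster colors; values near 1 mean extreme transitions.
#'
#' @param segA,segB \linkS4class{ColorSegmentation} objects on equal-size
#'   canvases.
#' @return Scalar in \code{[0, 1]}.
#' @export
colorEvolutionScore <- function(segA, segB) {
  if (!identical(segA@canvasDim, segB@canvasDim))
    stop("segmentations must share the same canvas size")
  swap <- nClusters(segA) > nClusters(segB)
  s1 <- if (swap) segB else segA   # fewer (or equal) clusters
  s2 <- if (swap) segA else segB
  k1 <- nClusters(s1); k2 <- nClusters(s2)
  iou <- matrix(0, k1, k2)
  for (i in seq_len(k1)) {
    mi <- s1@clusterMasks[[i]]
    for (j in seq_len(k2)) {
      mj <- s2@clusterMasks[[j]]
      inter <- sum(mi & mj)
      uni <- sum(mi | mj)
      iou[i, j] <- if (uni > 0) inter / uni else 0
    }
  }
  fallback <- all(iou == 0)
  if (fallback) {
    warning("no mask overlap between segmentations; ",
            "matching clusters by nearest centroid")
    for (i in seq_len(k1)) {
      dcent <- sqrt(colSums((t(s2@centroids) - s1@centroids[i, ])^2))
      iou[i, ] <- 1 / (1 + dcent)   # surrogate affinity
    }
  }
  # greedy matching, descending affinity; lower indices win ties
  pairs <- list()
  usedI <- rep(FALSE, k1); usedJ <- rep(FALSE, k2)
  ord <- order(-as.vector(iou),
               as.vector(row(iou)), as.vector(col(iou)))
  for (o in ord) {
    if (iou[o] <= 0 && !fallback) break
    i <- row(iou)[o]; j <- col(iou)[o]
    if (!usedI[i] && !usedJ[j]) {
      usedI[i] <- TRUE; usedJ[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) == 0L) return(0)
  dists <- vapply(pairs, function(p)
    sqrt(sum((s1@centroids[p[1], ] - s2@centroids[p[2], ])^2)), numeric(1))
  m <- length(pairs)
  .clamp(mean(dists) / .EVOLUTION_NORM * m / max(k1, k2), 0, 1)
}
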