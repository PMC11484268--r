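# Pipeline wiring: validated run configuration, stable per-stage seeds, and
# the synth -> normalize -> metrics -> flow -> analyze driver.

.CONFIG_KEYS <- c("seed", "stages", "input", "output", "maskFiles", "mmPerPx",
                  "confidenceCsv", "patchSize", "kMax", "alpha", "farneback",
                  "preset", "nFrames", "dispersionNorm", "evolutionNorm")

#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated list: the master
#' seed, the stages to run, input/output paths, the corner patch size for
#' color normalization, the clustering bounds, the optical-flow parameters
#' and the metric normalizer constants. Unknown keys are rejected by name.
#' The configuration is echoed verbatim as JSON into the output directory of
#' every run.
#'
#' @param ... Named configuration entries; see Details for the keys.
#' @details Recognized keys: \code{seed} (master seed, default 17),
#'   \code{stages} (subset of synth, normalize, metrics, flow, analyze),
#'   \code{input} (frame directory when not synthesizing), \code{output}
#'   (output directory), \code{maskFiles}, \code{mmPerPx},
#'   \code{confidenceCsv}, \code{patchSize} (20), \code{kMax} (6),
#'   \code{alpha} (0.05), \code{farneback} (\code{\link{flowParams}} list),
#'   \code{preset} ("nevus-to-melanoma"), \code{nFrames} (20),
#'   \code{dispersionNorm} and \code{evolutionNorm} (fixed metric
#'   normalizers, echoed for provenance).
#' @return A \code{RunConfig} list.
#' @export
runConfig <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(seed = 17L,
              stages = c("synth", "normalize", "metrics", "flow", "analyze"),
              input = NULL, output = tempfile("lesionflow_run_"),
              maskFiles = NULL, mmPerPx = NULL, confidenceCsv = NULL,
              patchSize = 20L, kMax = 6L, alpha = 0.05,
              farneback = flowParams(), preset = "nevus-to-melanoma",
              nFrames = 20L,
              dispersionNorm = .DISPERSION_NORM,
              evolutionNorm = .EVOLUTION_NORM)
  cfg[names(user)] <- user
  bad <- setdiff(cfg$stages,
                 c("synth", "normalize", "metrics", "flow", "analyze"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "RunConfig")
}

# Stable per-stage seed: polynomial hash of the stage name mixed with the
# master seed, kept inside the 32-bit integer range.
.stageSeed <- function(master, stage) {
  M <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% M
  as.integer((as.numeric(master) * 2654435 + h) %% M)
}

#' Run the lesion-progression pipeline
#'
#' Executes the requested stages in order: \code{synth} (generate a preset
#' progression), \code{normalize} (corner-referenced LAB color
#' normalization), \code{metrics} (per-frame trajectories), \code{flow}
#' (accumulated optical flow, heatmap, overlay, radial statistic) and
#' \code{analyze} (first-vs-last deltas, confidence correlations,
#' distribution summary). Any stage failure aborts with the stage name (and
#' frame index where applicable). All artifacts are written under
#' \code{config$output}, together with a verbatim JSON echo of the
#' configuration; rerunning with the same configuration reproduces them
#' byte for byte.
#'
#' @param config A \code{RunConfig} from \code{\link{runConfig}}.
#' @return Invisibly, a list with the in-memory results (sequence,
#'   trajectories, flow, statistics) and the paths of all written artifacts.
#' @importFrom jsonlite write_json
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- do.call(runConfig, config)
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  echo <- config
  echo$farneback <- unclass(echo$farneback)
  jsonlite::write_json(unclass(echo), file.path(out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  artifacts <- list(config = file.path(out, "config.json"))
  seqc <- NULL; conf <- NULL; gt <- NULL

  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("synth" %in% config$stages) {
    runStage("synth", function() {
      pspec <- switch(config$preset,
        "nevus-to-melanoma" = presetNevusToMelanoma(
          nFrames = config$nFrames,
          seed = .stageSeed(config$seed, "synth")),
        stop("unknown preset '", config$preset, "'"))
      res <- generateProgression(pspec)
      seqc <<- res$sequence; conf <<- res$confidence; gt <<- res$groundTruth
      fdir <- file.path(out, "frames"); mdir <- file.path(out, "masks")
      dir.create(fdir, showWarnings = FALSE)
      dir.create(mdir, showWarnings = FALSE)
      for (i in seq_len(length(seqc))) {
        writeLesionImage(seqc[[i]],
                         file.path(fdir, sprintf("f%03d.png", i - 1L)))
        writeMaskImage(frameMask(seqc[[i]]),
                       file.path(mdir, sprintf("f%03d_mask.png", i - 1L)))
      }
      writeConfidence(conf, file.path(out, "confidence.csv"))
      jsonlite::write_json(gt, file.path(out, "ground_truth.json"),
                           dataframe = "rows", digits = NA)
      artifacts$frames <<- fdir
      artifacts$confidence <<- file.path(out, "confidence.csv")
    })
  } else {
    if (is.null(config$input)) stop("config$input required without synth")
    seqc <- loadSequence(config$input, maskFiles = config$maskFiles,
                         mmPerPx = config$mmPerPx)
    if (!is.null(config$confidenceCsv))
      conf <- readConfidence(config$confidenceCsv)
  }

  if ("normalize" %in% config$stages) {
    runStage("normalize", function() {
      seqc <<- normalizeSequenceColors(seqc, patchSize = config$patchSize)
      ndir <- file.path(out, "normalized")
      dir.create(ndir, showWarnings = FALSE)
      for (i in seq_len(length(seqc)))
        writeLesionImage(seqc[[i]],
                         file.path(ndir, sprintf("f%03d.png", i - 1L)))
      artifacts$normalized <<- ndir
    })
  }

  traj <- NULL
  if ("metrics" %in% config$stages) {
    runStage("metrics", function() {
      traj <<- computeTrajectories(seqc,
                                   seed = .stageSeed(config$seed, "metrics"))
      writeMetrics(traj, file.path(out, "metrics.csv"))
      artifacts$metrics <<- file.path(out, "metrics.csv")
    })
  }

  acc <- NULL; flowStats <- NULL
  if ("flow" %in% config$stages) {
    runStage("flow", function() {
      acc <<- accumulateFlow(seqc, params = config$farneback)
      last <- seqc[[length(seqc)]]
      writeLesionImage(flowHeatmap(acc), file.path(out, "heatmap.png"))
      writeLesionImage(flowHeatmap(acc, overlayOn = last, quiver = TRUE),
                       file.path(out, "heatmap_overlay.png"))
      flowStats <<- list(
        radial_expansion = radialExpansionStat(acc, frameMask(last)),
        magnitude_max = max(flowMagnitude(acc)),
        magnitude_mean_lesion = mean(flowMagnitude(acc)[frameMask(last)]))
      jsonlite::write_json(flowStats, file.path(out, "flow_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$heatmap <<- file.path(out, "heatmap.png")
      artifacts$flowStats <<- file.path(out, "flow_stats.json")
    })
  }

  deltas <- NULL; correlations <- NULL; summary <- NULL
  if ("analyze" %in% config$stages) {
    runStage("analyze", function() {
      if (is.null(traj)) stop("metrics stage must run before analyze")
      deltas <<- firstLastDelta(traj)
      summary <<- distributionSummary(traj)
      jsonlite::write_json(deltas, file.path(out, "deltas.json"),
                           dataframe = "rows", digits = NA)
      jsonlite::write_json(summary, file.path(out, "summary.json"),
                           dataframe = "rows", digits = NA)
      artifacts$deltas <<- file.path(out, "deltas.json")
      artifacts$summary <<- file.path(out, "summary.json")
      if (!is.null(conf)) {
        correlations <<- correlateWithConfidence(traj, conf)
        utils::write.csv(correlations, file.path(out, "correlations.csv"),
                         row.names = FALSE, quote = FALSE)
        artifacts$correlations <<- file.path(out, "correlations.csv")
      }
    })
  }

  invisible(list(sequence = seqc, confidence = conf, trajectories = traj,
                 flow = acc, flowStats = flowStats, deltas = deltas,
                 correlations = correlations, summary = summary,
                 groundTruth = gt, artifacts = artifacts))
}
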