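# Image / mask / CSV input-output and sequence assembly.

# Read an image file into an H x W x 3 array of sRGB intensities [0, 255].
#' @importFrom EBImage readImage imageData
.readRgbArray <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file '", path,
                                           "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)          # (x = width, y = height[, channels])
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(a)[3] < 3L) a <- array(rep(a[, , 1], 3L), dim = c(dim(a)[1:2], 3L))
  out <- aperm(a, c(2, 1, 3)) * 255     # to (row, col, channel)
  round(.clamp(out, 0, 255))
}

# Read a mask file. Multi-channel masks are coerced by thresholding the
# channel mean at 128 (a warning is emitted).
.readMaskArray <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable mask file '", path,
                                           "': ", conditionMessage(e)))
  a <- EBImage::imageData(img) * 255
  if (length(dim(a)) == 3L) {
    warning("mask file '", path,
            "' has multiple channels; thresholding channel mean at 128")
    a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  }
  t(a) >= 128
}

#' Load a dermoscopic frame sequence
#'
#' Reads an ordered sequence of RGB frames (PNG/JPEG) from a directory or an
#' explicit file list. Frame order is the lexicographic filename sort unless
#' \code{orderFile} (a text file with one filename per line) is given. Masks
#' may be supplied as a parallel file vector or an \code{sprintf} template
#' applied to each frame's base name (e.g. \code{"masks/\%s_mask.png"});
#' without masks, each frame is segmented automatically by
#' \code{\link{segmentLesion}}.
#'
#' @param input Directory containing the frames, or a character vector of
#'   image file paths (at least 2).
#' @param maskFiles Optional character vector of mask paths (parallel to the
#'   frames) or a single \code{sprintf} template with one \code{\%s}.
#' @param mmPerPx Optional positive scalar, physical resolution in mm/pixel,
#'   applied to every frame.
#' @param orderFile Optional path to a text file fixing the frame order.
#' @return A \linkS4class{FrameSequence}.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' fr <- generateLesion(lesionSpec(seed = 1))
#' writeLesionImage(frameImage(fr), file.path(dir, "f000.png"))
#' writeLesionImage(frameImage(fr), file.path(dir, "f001.png"))
#' seq <- loadSequence(dir)
#' length(seq)
#' @export
loadSequence <- function(input, maskFiles = NULL, mmPerPx = NULL,
                         orderFile = NULL) {
  if (length(input) == 1L && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!is.null(maskFiles) && length(maskFiles) == 1L &&
        grepl("%s", maskFiles, fixed = TRUE)) {
      # don't pick up mask files living in the same directory
      files <- files[!grepl("mask", basename(files), ignore.case = TRUE)]
    }
    files <- sort(files, method = "radix")
  } else {
    files <- as.character(input)
  }
  if (!is.null(orderFile)) {
    ord <- readLines(orderFile)
    files <- file.path(dirname(files[1]), ord)
  }
  if (length(files) < 2L)
    stop("at least 2 readable image files are required, found ",
         length(files))
  if (!is.null(maskFiles) && length(maskFiles) == 1L &&
      grepl("%s", maskFiles, fixed = TRUE)) {
    base <- sub("\\.[^.]+$", "", basename(files))
    maskFiles <- sprintf(maskFiles, base)
  }
  if (!is.null(maskFiles) && length(maskFiles) != length(files))
    stop("maskFiles must match the number of frames")
  imgs <- lapply(files, .readRgbArray)
  d0 <- dim(imgs[[1]])[1:2]
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]])[1:2], d0))
      stop("dimension mismatch: '", files[i], "' is ",
           paste(dim(imgs[[i]])[1:2], collapse = " x "), ", expected ",
           paste(d0, collapse = " x "))
  }
  framesList <- vector("list", length(files))
  for (i in seq_along(files)) {
    mask <- if (is.null(maskFiles)) NULL else {
      m <- .readMaskArray(maskFiles[i])
      if (!identical(dim(m), d0))
        stop("mask dimension mismatch for '", maskFiles[i], "'")
      m
    }
    framesList[[i]] <- LesionFrame(imgs[[i]], mask = mask, mmPerPx = mmPerPx)
  }
  FrameSequence(framesList)
}

#' Write an RGB image to disk
#'
#' @param img \code{H x W x 3} array of sRGB intensities in \code{[0, 255]},
#'   or a \linkS4class{LesionFrame}.
#' @param path Output file; format from the extension (PNG or JPEG).
#' @return Invisibly, \code{path}.
#' @importFrom EBImage writeImage Image
#' @export
writeLesionImage <- function(img, path) {
  if (is(img, "LesionFrame")) img <- frameImage(img)
  a <- aperm(.clamp(img, 0, 255) / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask to disk
#'
#' Masks are stored as 8-bit single-channel PNG, 0 = background, 255 = lesion.
#'
#' @param mask Logical matrix.
#' @param path Output PNG file.
#' @return Invisibly, \code{path}.
#' @export
writeMaskImage <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Write a metric-trajectory table to CSV
#'
#' One row per frame with columns \code{frame_index} (0-based),
#' \code{asymmetry}, \code{border_gradient}, \code{convexity},
#' \code{color_dispersion}, \code{diameter}, \code{diameter_units} and
#' \code{color_evolution_from_first}. Values round-trip through
#' \code{\link{readMetrics}} to better than 1e-6.
#'
#' @param trajectories Data frame as returned by
#'   \code{\link{computeTrajectories}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @importFrom utils write.csv
#' @export
writeMetrics <- function(trajectories, path) {
  if (is.null(trajectories) || nrow(trajectories) == 0L)
    stop("trajectories must be non-empty")
  cols <- c("frame_index", "asymmetry", "border_gradient", "convexity",
            "color_dispersion", "diameter", "diameter_units",
            "color_evolution_from_first")
  missing <- setdiff(cols, names(trajectories))
  if (length(missing))
    stop("trajectories lacks columns: ", paste(missing, collapse = ", "))
  out <- trajectories[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 9))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metric-trajectory table written by \code{writeMetrics}
#'
#' @param path CSV path.
#' @return Data frame of per-frame metrics.
#' @importFrom utils read.csv
#' @export
readMetrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a classifier-confidence series
#'
#' Expects a CSV with a \code{confidence_nevus} column holding one value in
#' \code{[0, 1]} per frame (the confidence of a nevus diagnosis).
#'
#' @param path CSV path.
#' @return Numeric vector of confidences.
#' @export
readConfidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"confidence_nevus" %in% names(df))
    stop("confidence CSV must contain a 'confidence_nevus' column")
  v <- as.numeric(df$confidence_nevus)
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("confidence values must lie in [0, 1]")
  v
}

#' Write a classifier-confidence series
#'
#' @param conf Numeric vector in \code{[0, 1]}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeConfidence <- function(conf, path) {
  utils::write.csv(
    data.frame(frame_index = seq_along(conf) - 1L,
               confidence_nevus = signif(conf, 9)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
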