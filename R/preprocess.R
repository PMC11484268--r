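# Baseline lesion segmentation and corner-referenced CIELAB color
# normalization of frame sequences.

#' Segment the lesion in a dermoscopic image
#'
#' Deterministic baseline segmentation: the lesion is taken as the pixels
#' darker than an automatic global threshold (between-class variance
#' maximization, Otsu) on the luminance image, cleaned by morphological
#' closing (disk radius 3 px) and hole filling, reduced to the largest
#' 8-connected component. Pigmented lesions are darker than surrounding skin,
#' which is what the darker-side rule encodes. User-supplied masks always
#' override this baseline.
#'
#' @param image \code{H x W x 3} sRGB array in \code{[0, 255]} or a
#'   \linkS4class{LesionFrame}.
#' @return Logical \code{H x W} mask.
#' @examples
#' img <- array(200, dim = c(64, 64, 3))
#' img[20:44, 20:44, ] <- 60
#' mask <- segmentLesion(img)
#' sum(mask)
#' @importFrom EBImage otsu closing fillHull makeBrush Image
#' @export
segmentLesion <- function(image) {
  if (is(image, "LesionFrame")) image <- frameImage(image)
  gray <- .luminance(image) / 255
  if (max(gray) - min(gray) < 1e-6)
    stop("no lesion found: image is uniform")
  thr <- EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1))
  fg <- gray < thr
  if (!any(fg)) stop("no lesion found: empty foreground")
  fg <- EBImage::closing(fg * 1, EBImage::makeBrush(7, shape = "disc"))
  fg <- EBImage::fillHull(fg) > 0
  if (!any(fg)) stop("no lesion found: empty foreground")
  .largestComponent(fg)
}

#' Corner-based healthy-skin color reference
#'
#' Averages the RGB values over the union of the four
#' \code{patchSize x patchSize} corner patches of a frame and converts the
#' mean to CIELAB (D65). The corners are assumed to contain only healthy
#' skin; the reference anchors the color normalization of a sequence.
#'
#' @param image \code{H x W x 3} sRGB array or \linkS4class{LesionFrame}.
#' @param patchSize Corner patch side length in pixels (default 20). Must not
#'   exceed a quarter of the smaller image dimension.
#' @param sourceFrameIndex Integer bookkeeping tag (default 0 = first frame).
#' @return A \code{ColorReference}: list with elements \code{lab} (length-3
#'   CIELAB), \code{patchSize} and \code{sourceFrameIndex}.
#' @export
cornerColorReference <- function(image, patchSize = 20L,
                                 sourceFrameIndex = 0L) {
  if (is(image, "LesionFrame")) image <- frameImage(image)
  d <- dim(image)
  if (patchSize < 1L || patchSize > min(d[1], d[2]) / 4)
    stop("patchSize must be positive and at most min(H, W)/4")
  p <- patchSize
  rows <- c(seq_len(p), d[1] - p + seq_len(p))
  cols <- c(seq_len(p), d[2] - p + seq_len(p))
  patch <- image[rows, cols, , drop = FALSE]
  meanRGB <- apply(patch, 3, mean)
  structure(
    list(lab = as.numeric(.srgbToLab(matrix(meanRGB, 1))),
         patchSize = as.integer(patchSize),
         sourceFrameIndex = as.integer(sourceFrameIndex)),
    class = "ColorReference")
}

# Mean corner color of one frame in CIELAB.
.cornerLab <- function(image, patchSize) {
  cornerColorReference(image, patchSize)$lab
}

#' Normalize the colors of a frame sequence to its first frame
#'
#' Later frames of simulated sequences often drift in overall color. The
#' first frame's corner patches (healthy skin) define a CIELAB reference; for
#' every later frame, the offset \code{reference - frame_corner_mean} is
#' added uniformly to all pixels in LAB space and the frame is converted back
#' to sRGB with gamut clipping. Frame 1 is returned unchanged; lesion pixels
#' receive exactly the same offset as skin pixels.
#'
#' @param seq A \linkS4class{FrameSequence} with at least 2 frames.
#' @param patchSize Corner patch side length in pixels (default 20).
#' @return A color-normalized \linkS4class{FrameSequence} (masks and scales
#'   preserved).
#' @export
normalizeSequenceColors <- function(seq, patchSize = 20L) {
  if (length(seq) < 2L) stop("at least 2 frames required")
  ref <- cornerColorReference(seq[[1]], patchSize)$lab
  out <- frames(seq)
  for (i in 2:length(seq)) {
    fr <- out[[i]]
    img <- frameImage(fr)
    offset <- ref - .cornerLab(img, patchSize)
    lab <- .imageToLab(img)
    lab[, , 1] <- lab[, , 1] + offset[1]
    lab[, , 2] <- lab[, , 2] + offset[2]
    lab[, , 3] <- lab[, , 3] + offset[3]
    adj <- .clamp(.labToImage(lab), 0, 255)
    out[[i]] <- new("LesionFrame", image = adj, mask = frameMask(fr),
                    mmPerPx = fr@mmPerPx)
  }
  FrameSequence(out)
}
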