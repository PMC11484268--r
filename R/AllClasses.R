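#' @import methods
NULL

# ---------------------------------------------------------------------------
# LesionFrame: one dermoscopic RGB frame, its binary lesion mask, and an
# optional physical scale.
# ---------------------------------------------------------------------------

#' LesionFrame: a dermoscopic image with its lesion mask
#'
#' An S4 container for one frame of a lesion sequence: an RGB image stored as
#' an \code{H x W x 3} array of sRGB intensities in \code{[0, 255]}, a logical
#' \code{H x W} mask (\code{TRUE} = lesion), and an optional physical scale in
#' mm per pixel. All geometry in the package uses 1-based (row, col)
#' coordinates with pixel centers at integer positions.
#'
#' @slot image Numeric \code{H x W x 3} array, sRGB intensities in
#'   \code{[0, 255]}; \code{H, W >= 16}.
#' @slot mask Logical \code{H x W} matrix, \code{TRUE} marks lesion pixels.
#' @slot mmPerPx Numeric of length 0 (unknown) or 1 (finite, positive).
#'
#' @seealso \code{\link{LesionFrame}}, \code{\link{FrameSequence-class}}
#' @name LesionFrame-class
#' @rdname LesionFrame-class
#' @exportClass LesionFrame
setClass("LesionFrame",
  representation(image = "array", mask = "matrix", mmPerPx = "numeric"))

setValidity("LesionFrame", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    return("image must be an H x W x 3 array")
  if (d[1] < 16L || d[2] < 16L)
    return("image must be at least 16 x 16 pixels")
  if (anyNA(object@image) || min(object@image) < 0 || max(object@image) > 255)
    return("image intensities must lie in [0, 255]")
  if (!is.logical(object@mask))
    return("mask must be a logical matrix")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask dimensions must match the image")
  if (length(object@mmPerPx) > 1L)
    return("mmPerPx must have length 0 or 1")
  if (length(object@mmPerPx) == 1L &&
      (!is.finite(object@mmPerPx) || object@mmPerPx <= 0))
    return("mmPerPx must be finite and positive")
  TRUE
})

#' Construct a LesionFrame
#'
#' @param image \code{H x W x 3} numeric array of sRGB intensities in
#'   \code{[0, 255]}.
#' @param mask Logical \code{H x W} matrix, or \code{NULL} to derive one
#'   automatically with \code{\link{segmentLesion}}.
#' @param mmPerPx Optional positive scalar: physical resolution in mm/pixel.
#' @return A \linkS4class{LesionFrame}.
#' @examples
#' img <- array(200, dim = c(32, 32, 3))
#' img[10:22, 10:22, ] <- 60
#' fr <- LesionFrame(img)
#' sum(frameMask(fr))
#' @export
LesionFrame <- function(image, mask = NULL, mmPerPx = NULL) {
  image <- array(as.numeric(image), dim = dim(image))
  if (is.null(mask)) mask <- segmentLesion(image)
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  new("LesionFrame", image = image, mask = mask,
      mmPerPx = if (is.null(mmPerPx)) numeric(0) else as.numeric(mmPerPx))
}

#' @describeIn LesionFrame-class extract the RGB image array
#' @param object,x A \code{LesionFrame}.
#' @export
setGeneric("frameImage", function(x) standardGeneric("frameImage"))

#' @rdname LesionFrame-class
#' @export
setMethod("frameImage", "LesionFrame", function(x) x@image)

#' @describeIn LesionFrame-class extract the logical lesion mask
#' @export
setGeneric("frameMask", function(x) standardGeneric("frameMask"))

#' @rdname LesionFrame-class
#' @export
setMethod("frameMask", "LesionFrame", function(x) x@mask)

#' @describeIn LesionFrame-class physical scale (mm/pixel), or \code{NA} if unknown
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))

#' @rdname LesionFrame-class
#' @export
setMethod("mmPerPx", "LesionFrame", function(x)
  if (length(x@mmPerPx)) x@mmPerPx else NA_real_)

setMethod("show", "LesionFrame", function(object) {
  d <- dim(object@image)
  cat(sprintf("LesionFrame %d x %d, %d lesion px (%.1f%%)%s\n",
              d[1], d[2], sum(object@mask),
              100 * mean(object@mask),
              if (length(object@mmPerPx))
                sprintf(", %.4g mm/px", object@mmPerPx) else ""))
})

# ---------------------------------------------------------------------------
# FrameSequence: an ordered, registered sequence of LesionFrames.
# ---------------------------------------------------------------------------

#' FrameSequence: an ordered lesion image sequence
#'
#' Ordered list of \linkS4class{LesionFrame} objects sharing one canvas.
#' Frames are assumed registered (same canvas, same lesion); evolution and
#' flow computations require at least two frames.
#'
#' @slot frames List of \linkS4class{LesionFrame} objects with equal
#'   dimensions.
#' @name FrameSequence-class
#' @rdname FrameSequence-class
#' @exportClass FrameSequence
setClass("FrameSequence", representation(frames = "list"))

setValidity("FrameSequence", function(object) {
  if (length(object@frames) < 1L) return("at least one frame required")
  ok <- vapply(object@frames, is, logical(1), class2 = "LesionFrame")
  if (!all(ok)) return("all elements must be LesionFrame objects")
  dims <- vapply(object@frames, function(f) dim(f@image)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all frames must share the same dimensions")
  TRUE
})

#' Construct a FrameSequence
#'
#' @param frames List of \linkS4class{LesionFrame} objects (equal canvas).
#' @return A \linkS4class{FrameSequence}.
#' @export
FrameSequence <- function(frames) new("FrameSequence", frames = frames)

#' @describeIn FrameSequence-class list of frames
#' @param x,object A \code{FrameSequence}.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameSequence-class
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname FrameSequence-class
#' @export
setMethod("length", "FrameSequence", function(x) length(x@frames))

#' @rdname FrameSequence-class
#' @param i Frame index (1-based).
#' @param j,... Unused.
#' @export
setMethod("[[", "FrameSequence", function(x, i, j, ...) x@frames[[i]])

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1]]@image)
  cat(sprintf("FrameSequence of %d frames, %d x %d\n",
              length(object@frames), d[1], d[2]))
})

# ---------------------------------------------------------------------------
# ColorSegmentation: per-pixel color cluster assignment of the lesion.
# ---------------------------------------------------------------------------

#' ColorSegmentation: color clustering of lesion pixels
#'
#' Result of \code{\link{colorSegment}}: every lesion pixel carries a cluster
#' label; clusters have linear-RGB centroids in the unit cube and weights
#' (pixel fractions) summing to 1.
#'
#' @slot labels Integer vector, cluster index in \code{1..k} per lesion pixel.
#' @slot pixelIndex Integer vector of linear indices into the \code{H x W}
#'   canvas, parallel to \code{labels}.
#' @slot centroids \code{k x 3} matrix of linear-RGB cluster centers.
#' @slot weights Numeric length-\code{k}, pixel fractions summing to 1.
#' @slot clusterMasks List of \code{k} logical \code{H x W} matrices.
#' @slot canvasDim Integer \code{c(H, W)}.
#' @name ColorSegmentation-class
#' @rdname ColorSegmentation-class
#' @exportClass ColorSegmentation
setClass("ColorSegmentation",
  representation(labels = "integer", pixelIndex = "integer",
                 centroids = "matrix", weights = "numeric",
                 clusterMasks = "list", canvasDim = "integer"))

setValidity("ColorSegmentation", function(object) {
  k <- nrow(object@centroids)
  if (k < 1L) return("at least one cluster required")
  if (ncol(object@centroids) != 3L) return("centroids must be k x 3")
  if (length(object@weights) != k) return("weights length must equal k")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (length(object@labels) != length(object@pixelIndex))
    return("labels and pixelIndex must be parallel")
  if (any(object@labels < 1L | object@labels > k))
    return("labels out of range")
  if (length(object@clusterMasks) != k)
    return("one cluster mask per cluster required")
  TRUE
})

#' @describeIn ColorSegmentation-class number of color clusters
#' @param x,object A \code{ColorSegmentation}.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ColorSegmentation-class
#' @export
setMethod("nClusters", "ColorSegmentation", function(x) nrow(x@centroids))

#' @describeIn ColorSegmentation-class \code{k x 3} linear-RGB centroid matrix
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))

#' @rdname ColorSegmentation-class
#' @export
setMethod("clusterCentroids", "ColorSegmentation", function(x) x@centroids)

#' @describeIn ColorSegmentation-class cluster pixel fractions
#' @export
setGeneric("clusterWeights", function(x) standardGeneric("clusterWeights"))

#' @rdname ColorSegmentation-class
#' @export
setMethod("clusterWeights", "ColorSegmentation", function(x) x@weights)

#' @describeIn ColorSegmentation-class list of per-cluster logical masks
#' @export
setGeneric("clusterMasks", function(x) standardGeneric("clusterMasks"))

#' @rdname ColorSegmentation-class
#' @export
setMethod("clusterMasks", "ColorSegmentation", function(x) x@clusterMasks)

setMethod("show", "ColorSegmentation", function(object) {
  cat(sprintf("ColorSegmentation: %d cluster(s) over %d lesion pixels\n",
              nrow(object@centroids), length(object@labels)))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
})

# ---------------------------------------------------------------------------
# AccumulatedFlow: vector sum of consecutive-pair optical flow fields.
# ---------------------------------------------------------------------------

#' AccumulatedFlow: summed optical flow over a sequence
#'
#' Elementwise vector sum of the per-pair dense optical flow fields of a
#' sequence, with its magnitude map. Summing vectors (rather than magnitudes)
#' deliberately lets opposing per-step motions cancel, highlighting net
#' change.
#'
#' @slot vectors \code{H x W x 2} array of (dx, dy) displacements in pixels
#'   (x rightward = columns, y downward = rows).
#' @slot magnitude \code{H x W} Euclidean norm of the summed vectors.
#' @name AccumulatedFlow-class
#' @rdname AccumulatedFlow-class
#' @exportClass AccumulatedFlow
setClass("AccumulatedFlow",
  representation(vectors = "array", magnitude = "matrix"))

setValidity("AccumulatedFlow", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 3L || d[3] != 2L) return("vectors must be H x W x 2")
  if (!all(is.finite(object@vectors))) return("vectors must be finite")
  if (!identical(dim(object@magnitude), d[1:2]))
    return("magnitude dimensions must match vectors")
  mag <- sqrt(object@vectors[, , 1]^2 + object@vectors[, , 2]^2)
  if (max(abs(mag - object@magnitude)) > 1e-9)
    return("magnitude must equal the norm of vectors")
  TRUE
})

.AccumulatedFlow <- function(vectors) {
  new("AccumulatedFlow", vectors = vectors,
      magnitude = sqrt(vectors[, , 1]^2 + vectors[, , 2]^2))
}

#' @describeIn AccumulatedFlow-class the \code{H x W x 2} displacement array
#' @param x,object An \code{AccumulatedFlow}.
#' @export
setGeneric("flowVectors", function(x) standardGeneric("flowVectors"))

#' @rdname AccumulatedFlow-class
#' @export
setMethod("flowVectors", "AccumulatedFlow", function(x) x@vectors)

#' @describeIn AccumulatedFlow-class the \code{H x W} magnitude map
#' @export
setGeneric("flowMagnitude", function(x) standardGeneric("flowMagnitude"))

#' @rdname AccumulatedFlow-class
#' @export
setMethod("flowMagnitude", "AccumulatedFlow", function(x) x@magnitude)

setMethod("show", "AccumulatedFlow", function(object) {
  cat(sprintf(
    "AccumulatedFlow %d x %d, magnitude median %.3f px, max %.3f px\n",
    nrow(object@magnitude), ncol(object@magnitude),
    stats::median(object@magnitude), max(object@magnitude)))
})
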