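# Per-frame ABCDE-rule metrics: moment-ellipse fit, asymmetry via mirrored
# halves, border gradient sharpness, convexity, and major-axis diameter.
# (Color clustering and the color metrics live in color_cluster.R.)

# Maximum magnitude attainable by the 3x3 Sobel pair at data range 255
# (support-function maximum over all images with intensities in [0, 255]:
# gx = 1020, gy = 510 at the optimal direction, giving 510 * sqrt(5)).
.SOBEL_MAX_255 <- 510 * sqrt(5)

.SOBEL_X <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (cols)
.SOBEL_Y <- t(.SOBEL_X)                                          # d/dy (rows)

#' Fit the moment-equivalent ellipse of a lesion mask
#'
#' Center, axis lengths and orientation of the ellipse with the same
#' second-order central moments as the mask pixels (the standard
#' moment-equivalent ellipse; axis length = 4 sqrt(eigenvalue) so that a
#' filled ellipse recovers its own axes).
#'
#' @param mask Logical matrix; reduced to its largest 8-connected component.
#' @return A \code{LesionEllipse}: list with \code{center} (row, col),
#'   \code{majorAxisLen}, \code{minorAxisLen} (px) and \code{orientation}
#'   (radians of the major axis versus the image x-axis, in
#'   \code{[-pi/2, pi/2)}; y points down the rows).
#' @export
fitLesionEllipse <- function(mask) {
  mask <- .largestComponent(mask)
  pts <- which(mask, arr.ind = TRUE)
  y <- pts[, 1]; x <- pts[, 2]
  xc <- mean(x); yc <- mean(y)
  cxx <- mean((x - xc)^2); cyy <- mean((y - yc)^2)
  cxy <- mean((x - xc) * (y - yc))
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  lam1 <- tr / 2 + disc; lam2 <- tr / 2 - disc
  if (lam2 <= 1e-9 && length(y) > 2L)
    stop("degenerate mask: pixels are collinear")
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  if (theta >= pi / 2) theta <- theta - pi
  if (theta < -pi / 2) theta <- theta + pi
  structure(list(center = c(yc, xc),
                 majorAxisLen = 4 * sqrt(lam1),
                 minorAxisLen = 4 * sqrt(max(0, lam2)),
                 orientation = theta),
            class = "LesionEllipse")
}

# Rotate a matrix about `center` = (row, col) so that the direction `theta`
# (radians vs x-axis) maps onto the output's horizontal axis. Canvas size is
# preserved; out-of-canvas samples take `fill`.
.rotateAbout <- function(m, center, theta, bilinear = TRUE, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  grid <- expand.grid(r = seq_len(h), c = seq_len(w))
  dx <- grid$c - center[2]; dy <- grid$r - center[1]
  sx <- center[2] + cos(theta) * dx - sin(theta) * dy
  sy <- center[1] + sin(theta) * dx + cos(theta) * dy
  inside <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  vals <- rep(fill, h * w)
  if (bilinear) {
    vals[inside] <- .bilinearSample(m, sy[inside], sx[inside])
  } else {
    vals[inside] <- m[cbind(round(sy[inside]), round(sx[inside]))]
  }
  matrix(vals, h, w)
}

# One mirrored-half dissimilarity: split `gray` at `pos` along dimension
# `dim` (1 = split into top/bottom at a row, 2 = left/right at a column),
# order both halves outward from the split, pad the shorter with the
# background level, and return 1 - SSIM clamped to [0, 1].
.halfDissimilarity <- function(gray, mask, pos, dim, bg) {
  if (dim == 2L) { gray <- t(gray); mask <- t(mask) }
  h <- nrow(gray)
  # halves mirror about the line sr + 0.5, so take the split line nearest
  # to the ellipse-center coordinate
  sr <- .clamp(floor(pos), 1L, h - 1L)
  top <- gray[sr:1, , drop = FALSE]                 # row 1 = at the split
  bot <- gray[(sr + 1L):h, , drop = FALSE]
  n <- max(nrow(top), nrow(bot))
  pad <- function(m) {
    if (nrow(m) < n)
      m <- rbind(m, matrix(bg, n - nrow(m), ncol(m)))
    m
  }
  s <- .ssim(pad(top), pad(bot))
  .clamp(1 - s, 0, 1)
}

#' Asymmetry score of a lesion
#'
#' Measures how dissimilar the two lesion halves are about each principal
#' axis. The image (luminance) and mask are rotated about the ellipse center
#' so the major axis is horizontal (bilinear for the image, nearest for the
#' mask), cropped to the rotated mask's bounding box, split at the ellipse
#' center row, and the mirrored halves are compared by SSIM (grayscale,
#' 7x7 window, data range 255); the same is done about the minor axis
#' (split at the center column). The score is the mean of the two
#' dissimilarities \code{1 - SSIM}, clamped to \code{[0, 1]}: 0 = perfect
#' mirror symmetry, 1 = complete asymmetry.
#'
#' @param image \code{H x W x 3} sRGB array in \code{[0, 255]}.
#' @param mask Logical lesion mask (largest component used).
#' @return Scalar in \code{[0, 1]}.
#' @export
asymmetryScore <- function(image, mask) {
  mask <- .largestComponent(mask)
  ell <- fitLesionEllipse(mask)
  gray <- .luminance(image)
  grayR <- .rotateAbout(gray, ell$center, ell$orientation, bilinear = TRUE,
                        fill = 0)
  maskR <- .rotateAbout(mask * 1, ell$center, ell$orientation,
                        bilinear = FALSE, fill = 0) > 0.5
  pts <- which(maskR, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("lesion too small after rotation")
  r1 <- min(pts[, 1]); r2 <- max(pts[, 1])
  c1 <- min(pts[, 2]); c2 <- max(pts[, 2])
  if (r2 - r1 + 1L < 16L || c2 - c1 + 1L < 16L)
    stop("lesion too small after rotation (bounding box < 16 px)")
  crop <- grayR[r1:r2, c1:c2, drop = FALSE]
  cropM <- maskR[r1:r2, c1:c2, drop = FALSE]
  bg <- if (any(!cropM)) stats::median(crop[!cropM]) else mean(crop)
  dMajor <- .halfDissimilarity(crop, cropM, ell$center[1] - r1 + 1, 1L, bg)
  dMinor <- .halfDissimilarity(crop, cropM, ell$center[2] - c1 + 1, 2L, bg)
  mean(c(dMajor, dMinor))
}

# Outer contour of the largest component as an m x 2 matrix of 1-based
# (row, col) pixel coordinates, traced in order.
#' @importFrom EBImage ocontour Image
.outerContour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) stop("mask has no contour")
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  pts + 1L   # ocontour is 0-based in matrix index order
}

#' Border gradient score of a lesion
#'
#' Mean normalized gradient magnitude along the lesion contour. The
#' luminance image is filtered with the 3x3 Sobel pair; the magnitude map is
#' divided by the maximum magnitude attainable by that operator at data
#' range 255 (a fixed constant, so scores are comparable across frames), and
#' sampled bilinearly at the traced outer-contour points of the mask. High
#' values mean sharp, well-defined borders; 0 means no intensity transition.
#'
#' @param image \code{H x W x 3} sRGB array in \code{[0, 255]}.
#' @param mask Logical lesion mask (largest component used).
#' @return Scalar in \code{[0, 1]}.
#' @export
borderGradientScore <- function(image, mask) {
  mask <- .largestComponent(mask)
  gray <- .luminance(image)
  gx <- .correlate2d(gray, .SOBEL_X)
  gy <- .correlate2d(gray, .SOBEL_Y)
  mag <- sqrt(gx^2 + gy^2) / .SOBEL_MAX_255
  ct <- .outerContour(mask)
  if (nrow(ct) < 8L) stop("contour has fewer than 8 points")
  mean(.bilinearSample(mag, ct[, 1], ct[, 2]))
}

# Count pixel centers inside (or on) the convex hull of a point set.
# `hull` is the vertex matrix (x, y) in order; vectorized half-plane test.
.hullPixelCount <- function(hullXY, h, w) {
  nv <- nrow(hullXY)
  if (nv < 3L) return(NA_integer_)   # degenerate hull
  # ensure counter-clockwise orientation (positive signed area)
  x <- hullXY[, 1]; y <- hullXY[, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) { hullXY <- hullXY[nv:1, , drop = FALSE] }
  x <- hullXY[, 1]; y <- hullXY[, 2]
  rmin <- max(1L, floor(min(y))); rmax <- min(h, ceiling(max(y)))
  cmin <- max(1L, floor(min(x))); cmax <- min(w, ceiling(max(x)))
  grid <- expand.grid(py = rmin:rmax, px = cmin:cmax)
  inside <- rep(TRUE, nrow(grid))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (x[j] - x[i]) * (grid$py - y[i]) - (y[j] - y[i]) * (grid$px - x[i])
    inside <- inside & (cross >= -1e-9)
    if (!any(inside)) break
  }
  sum(inside)
}

#' Convexity score of a lesion mask
#'
#' Ratio of the lesion pixel count to the pixel count of its filled convex
#' hull (pixel centers inside or on the hull of the lesion pixel centers).
#' Equals 1 for convex shapes; indentations lower it.
#'
#' @param mask Logical lesion mask (largest component used).
#' @return Scalar in \code{(0, 1]}.
#' @examples
#' m <- matrix(FALSE, 64, 64); m[20:40, 20:40] <- TRUE
#' convexityScore(m)  # a filled rectangle is its own hull: exactly 1
#' @importFrom grDevices chull
#' @export
convexityScore <- function(mask) {
  mask <- .largestComponent(mask)
  pts <- which(mask, arr.ind = TRUE)
  hullIdx <- grDevices::chull(pts[, 2], pts[, 1])
  hullXY <- cbind(pts[hullIdx, 2], pts[hullIdx, 1])
  hullArea <- .hullPixelCount(hullXY, nrow(mask), ncol(mask))
  if (is.na(hullArea)) return(1)     # collinear pixels: hull = the pixels
  nrow(pts) / hullArea
}

#' Lesion diameter along the major axis
#'
#' Intersects the infinite line through the moment-ellipse center along the
#' major-axis orientation with the traced outer contour of the mask and
#' returns the distance between the two extreme intersection points. If a
#' physical scale is supplied the length is converted to millimetres.
#'
#' @param mask Logical lesion mask (largest component used).
#' @param mmPerPx Optional positive scalar (mm/pixel).
#' @return List with \code{length} (px or mm) and \code{units}
#'   (\code{"px"} or \code{"mm"}).
#' @export
lesionDiameter <- function(mask, mmPerPx = NULL) {
  mask <- .largestComponent(mask)
  ell <- fitLesionEllipse(mask)
  ux <- cos(ell$orientation); uy <- sin(ell$orientation)
  ct <- .outerContour(mask)
  dx <- ct[, 2] - ell$center[2]; dy <- ct[, 1] - ell$center[1]
  tproj <- ux * dx + uy * dy        # position along the axis
  sperp <- -uy * dx + ux * dy       # signed offset from the axis line
  m <- nrow(ct)
  nxt <- c(2:m, 1L)
  s1 <- sperp; s2 <- sperp[nxt]
  crossing <- (s1 <= 0 & s2 > 0) | (s1 >= 0 & s2 < 0) | (s1 == 0 & s2 == 0)
  tAt <- numeric(0)
  if (any(crossing)) {
    idx <- which(crossing)
    den <- s1[idx] - s2[idx]
    w <- ifelse(abs(den) > 1e-12, s1[idx] / den, 0.5)
    tAt <- tproj[idx] + (tproj[nxt][idx] - tproj[idx]) * w
  }
  if (length(tAt) >= 2L) {
    len <- max(tAt) - min(tAt)
  } else {
    warning("major-axis line misses the contour; ",
            "falling back to extreme mask pixels along the axis direction")
    pts <- which(mask, arr.ind = TRUE)
    tAll <- ux * (pts[, 2] - ell$center[2]) + uy * (pts[, 1] - ell$center[1])
    len <- max(tAll) - min(tAll)
  }
  if (!is.null(mmPerPx) && is.finite(mmPerPx) && mmPerPx > 0) {
    list(length = len * mmPerPx, units = "mm")
  } else {
    list(length = len, units = "px")
  }
}

#' Compute the per-frame metric vector
#'
#' Bundles the five per-frame lesion metrics: asymmetry, border gradient,
#' convexity, color dispersion (with its unimodality-gated color
#' segmentation) and diameter. Color evolution is a sequence-level quantity
#' and is computed by \code{\link{computeTrajectories}}.
#'
#' @param frame A \linkS4class{LesionFrame}.
#' @param seed Integer seed controlling the color clustering.
#' @return One-row data frame with columns \code{asymmetry},
#'   \code{border_gradient}, \code{convexity}, \code{color_dispersion},
#'   \code{diameter} and \code{diameter_units}.
#' @export
metricVector <- function(frame, seed = 17L) {
  seg <- colorSegment(frameImage(frame), frameMask(frame), seed = seed)
  .metricRow(frame, seg)
}

# Metric vector given a precomputed color segmentation (reused by
# computeTrajectories so segmentations are computed once per frame).
.metricRow <- function(frame, seg) {
  img <- frameImage(frame); mask <- frameMask(frame)
  dia <- lesionDiameter(mask, if (length(frame@mmPerPx)) frame@mmPerPx else NULL)
  data.frame(
    asymmetry = asymmetryScore(img, mask),
    border_gradient = borderGradientScore(img, mask),
    convexity = convexityScore(mask),
    color_dispersion = colorDispersionScore(img, mask, seg),
    diameter = dia$length,
    diameter_units = dia$units,
    stringsAsFactors = FALSE)
}
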