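# Dense optical flow by polynomial expansion (Farneback), accumulation over
# a sequence, heatmap/overlay rendering, and a radial-expansion summary.
#
# Each image neighborhood is approximated by a quadratic polynomial
# f(u) ~ c + b'u + u'Au estimated with a Gaussian-weighted least-squares fit
# (separable correlations); the displacement between two frames follows from
# the polynomial coefficients, aggregated over a box window and iterated
# over an image pyramid.

#' Optical-flow parameter set
#'
#' The standard parameterization of the Farneback estimator, pinned for
#' determinism: image pyramid with the given scale and level count, box
#' aggregation window, fixed-point iterations per level, and the size/sigma
#' of the Gaussian applicability used by the polynomial expansion.
#'
#' @param pyramidScale Downsampling factor between pyramid levels
#'   (default 0.5).
#' @param levels Number of pyramid levels (default 3).
#' @param window Side of the box aggregation window in px (default 15).
#' @param iterations Displacement iterations per level (default 3).
#' @param polyN Size of the polynomial-expansion neighborhood (default 5).
#' @param polySigma Gaussian applicability sigma (default 1.2).
#' @return Named list of parameters.
#' @export
flowParams <- function(pyramidScale = 0.5, levels = 3L, window = 15L,
                       iterations = 3L, polyN = 5L, polySigma = 1.2) {
  list(pyramidScale = pyramidScale, levels = as.integer(levels),
       window = as.integer(window), iterations = as.integer(iterations),
       polyN = as.integer(polyN), polySigma = polySigma)
}

# Quadratic polynomial expansion of a grayscale image.
# Returns per-pixel coefficient matrices: b1, b2 (gradient), a11, a22, a12
# where f(p + (x, y)) ~ c + b1 x + b2 y + a11 x^2 + a22 y^2 + a12 xy.
.polyExpansion <- function(f, n = 5L, sigma = 1.2) {
  r <- (n - 1L) %/% 2L
  u <- seq(-r, r)
  a <- exp(-u^2 / (2 * sigma^2))
  # 6x6 metric of the basis (1, x, y, x^2, y^2, xy) under the applicability
  ax <- rep(a, each = n); ay <- rep(a, times = n)
  w2 <- ax * ay
  X <- rep(u, each = n); Y <- rep(u, times = n)
  B <- cbind(1, X, Y, X^2, Y^2, X * Y)
  G <- crossprod(B, B * w2)
  Ginv <- solve(G)
  # separable correlations of f with applicability-weighted monomials
  v1  <- .sepCorrelate(f, a, a)
  vx  <- .sepCorrelate(f, a, a * u)
  vy  <- .sepCorrelate(f, a * u, a)
  vxx <- .sepCorrelate(f, a, a * u^2)
  vyy <- .sepCorrelate(f, a * u^2, a)
  vxy <- .sepCorrelate(f, a * u, a * u)
  lin <- function(row) {
    Ginv[row, 1] * v1 + Ginv[row, 2] * vx + Ginv[row, 3] * vy +
      Ginv[row, 4] * vxx + Ginv[row, 5] * vyy + Ginv[row, 6] * vxy
  }
  list(b1 = lin(2), b2 = lin(3), a11 = lin(4), a22 = lin(5),
       a12 = lin(6) / 2)
}

# One-level displacement refinement between two polynomial expansions.
.flowIterate <- function(e1, e2, dx, dy, window, iterations) {
  h <- nrow(e1$b1); w <- ncol(e1$b1)
  grid <- expand.grid(r = seq_len(h), c = seq_len(w))
  for (it in seq_len(iterations)) {
    sr <- grid$r + as.vector(dy)
    sc <- grid$c + as.vector(dx)
    samp <- function(m) matrix(.bilinearSample(m, sr, sc), h, w)
    a11 <- (e1$a11 + samp(e2$a11)) / 2
    a22 <- (e1$a22 + samp(e2$a22)) / 2
    a12 <- (e1$a12 + samp(e2$a12)) / 2
    dbx <- -0.5 * (samp(e2$b1) - e1$b1) + a11 * dx + a12 * dy
    dby <- -0.5 * (samp(e2$b2) - e1$b2) + a12 * dx + a22 * dy
    g11 <- .boxFilter(a11^2 + a12^2, window)
    g12 <- .boxFilter(a12 * (a11 + a22), window)
    g22 <- .boxFilter(a12^2 + a22^2, window)
    h1 <- .boxFilter(a11 * dbx + a12 * dby, window)
    h2 <- .boxFilter(a12 * dbx + a22 * dby, window)
    det <- g11 * g22 - g12^2
    ok <- det > 1e-12
    dx <- ifelse(ok, (g22 * h1 - g12 * h2) / det, 0)
    dy <- ifelse(ok, (g11 * h2 - g12 * h1) / det, 0)
    # displacements beyond the aggregation window are outside the
    # estimator's pull-in range; clamp ill-conditioned solutions
    dx <- .clamp(dx, -window, window)
    dy <- .clamp(dy, -window, window)
  }
  list(dx = dx, dy = dy)
}

# Gaussian-smoothed downsampling for the pyramid.
#' @importFrom EBImage gblur
.pyrDown <- function(m, scale) {
  sm <- EBImage::gblur(m, sigma = 1)
  .resizeBilinear(sm, max(8L, round(nrow(m) * scale)),
                  max(8L, round(ncol(m) * scale)))
}

#' Dense optical flow between two frames
#'
#' Estimates the per-pixel apparent motion from \code{frameA} to
#' \code{frameB} on the luminance images, using quadratic polynomial
#' expansion with pyramidal, iterative displacement refinement. The result
#' is deterministic for fixed inputs and parameters.
#'
#' @param frameA,frameB \code{H x W x 3} sRGB arrays in \code{[0, 255]} or
#'   \linkS4class{LesionFrame} objects of equal dimensions.
#' @param params Parameter list from \code{\link{flowParams}}.
#' @return \code{H x W x 2} array: \code{[,,1]} = dx (columns, rightward),
#'   \code{[,,2]} = dy (rows, downward), in pixels.
#' @export
farnebackFlow <- function(frameA, frameB, params = flowParams()) {
  if (is(frameA, "LesionFrame")) frameA <- frameImage(frameA)
  if (is(frameB, "LesionFrame")) frameB <- frameImage(frameB)
  if (!identical(dim(frameA)[1:2], dim(frameB)[1:2]))
    stop("frames must share the same dimensions")
  g1 <- .luminance(frameA); g2 <- .luminance(frameB)
  pyr1 <- list(g1); pyr2 <- list(g2)
  for (l in seq_len(params$levels - 1L)) {
    pyr1[[l + 1L]] <- .pyrDown(pyr1[[l]], params$pyramidScale)
    pyr2[[l + 1L]] <- .pyrDown(pyr2[[l]], params$pyramidScale)
  }
  dx <- dy <- NULL
  for (l in rev(seq_len(params$levels))) {
    f1 <- pyr1[[l]]; f2 <- pyr2[[l]]
    h <- nrow(f1); w <- ncol(f1)
    if (is.null(dx)) {
      dx <- matrix(0, h, w); dy <- matrix(0, h, w)
    } else {
      fac <- 1 / params$pyramidScale
      dx <- .resizeBilinear(dx, h, w) * fac
      dy <- .resizeBilinear(dy, h, w) * fac
    }
    e1 <- .polyExpansion(f1, params$polyN, params$polySigma)
    e2 <- .polyExpansion(f2, params$polyN, params$polySigma)
    res <- .flowIterate(e1, e2, dx, dy, params$window, params$iterations)
    dx <- res$dx; dy <- res$dy
  }
  out <- array(0, dim = c(nrow(g1), ncol(g1), 2L))
  out[, , 1] <- dx; out[, , 2] <- dy
  out
}

#' Accumulate optical flow over a sequence
#'
#' Elementwise vector sum of the dense flow fields of all consecutive frame
#' pairs. Summing vectors rather than magnitudes means opposing per-step
#' motions cancel: the map highlights net change at the cost of per-step
#' directional information.
#'
#' @param seq A \linkS4class{FrameSequence} with at least 2 frames.
#' @param params Parameter list from \code{\link{flowParams}}.
#' @return An \linkS4class{AccumulatedFlow}.
#' @export
accumulateFlow <- function(seq, params = flowParams()) {
  if (length(seq) < 2L) stop("at least 2 frames required")
  total <- NULL
  for (i in seq_len(length(seq) - 1L)) {
    fl <- farnebackFlow(seq[[i]], seq[[i + 1L]], params)
    total <- if (is.null(total)) fl else total + fl
  }
  .AccumulatedFlow(total)
}

# Blue -> green -> red colormap for t in [0, 1]; returns n x 3 sRGB rows.
.bgrColormap <- function(t) {
  t <- .clamp(t, 0, 1)
  lo <- t < 0.5
  s <- ifelse(lo, t * 2, (t - 0.5) * 2)
  r <- ifelse(lo, 0, s * 255)
  g <- ifelse(lo, s * 255, (1 - s) * 255)
  b <- ifelse(lo, (1 - s) * 255, 0)
  cbind(r, g, b)
}

# Draw a line segment into an RGB array by dense sampling.
.drawSegment <- function(img, r0, c0, r1, c1, color = c(0, 0, 0)) {
  len <- max(abs(r1 - r0), abs(c1 - c0), 1)
  ts <- seq(0, 1, length.out = ceiling(len * 2) + 1)
  rr <- round(r0 + ts * (r1 - r0)); cc <- round(c0 + ts * (c1 - c0))
  keep <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  for (ch in 1:3) img[cbind(rr[keep], cc[keep], ch)] <- color[ch]
  img
}

#' Render an accumulated-flow heatmap
#'
#' Min-max scales the magnitude map to \code{[0, 1]} and maps it through a
#' blue-green-red colormap; optionally alpha-blends the heatmap onto a
#' context image (typically the last frame) and/or draws the flow vectors on
#' a sparse grid (quiver rendering). The input object is never modified.
#'
#' @param acc An \linkS4class{AccumulatedFlow}.
#' @param overlayOn Optional \code{H x W x 3} sRGB array or
#'   \linkS4class{LesionFrame} of matching size to blend onto.
#' @param alpha Heatmap opacity for the overlay (default 0.5).
#' @param quiver If \code{TRUE}, draw subsampled flow vectors.
#' @param quiverStride Grid stride in px for the quiver (default 16).
#' @return \code{H x W x 3} sRGB array in \code{[0, 255]}.
#' @export
flowHeatmap <- function(acc, overlayOn = NULL, alpha = 0.5, quiver = FALSE,
                        quiverStride = 16L) {
  mag <- flowMagnitude(acc)
  rng <- range(mag)
  t <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else mag * 0
  cols <- .bgrColormap(as.vector(t))
  heat <- array(cols, dim = c(nrow(mag), ncol(mag), 3L))
  if (!is.null(overlayOn)) {
    if (is(overlayOn, "LesionFrame")) overlayOn <- frameImage(overlayOn)
    if (!identical(dim(overlayOn)[1:2], dim(mag)))
      stop("overlay image dimensions must match the flow field")
    heat <- alpha * heat + (1 - alpha) * overlayOn
  }
  if (quiver) {
    v <- flowVectors(acc)
    rs <- seq(quiverStride %/% 2L, nrow(mag), by = quiverStride)
    cs <- seq(quiverStride %/% 2L, ncol(mag), by = quiverStride)
    scale <- if (max(mag) > 0) quiverStride * 0.45 / max(mag) else 0
    for (r in rs) for (c in cs) {
      heat <- .drawSegment(heat, r, c, r + v[r, c, 2] * scale,
                           c + v[r, c, 1] * scale)
    }
  }
  .clamp(heat, 0, 255)
}

#' Radial expansion statistic of accumulated flow
#'
#' Mean, over a band straddling the lesion boundary (mask dilated minus
#' eroded with a 5-px disc), of the dot product between the accumulated flow
#' vector and the outward unit radial direction from the mask centroid.
#' Positive values indicate net outward expansion of the lesion boundary;
#' negative values indicate contraction. Rigid translations largely cancel
#' around the boundary.
#'
#' @param acc An \linkS4class{AccumulatedFlow}.
#' @param mask Logical lesion mask (largest component used).
#' @return Scalar, in pixels (net outward displacement).
#' @importFrom EBImage dilate erode makeBrush
#' @export
radialExpansionStat <- function(acc, mask) {
  mask <- .largestComponent(mask)
  brush <- EBImage::makeBrush(5, shape = "disc")
  band <- (EBImage::dilate(mask * 1, brush) > 0) &
    !(EBImage::erode(mask * 1, brush) > 0)
  if (!any(band)) stop("empty boundary band")
  pts <- which(mask, arr.ind = TRUE)
  cc <- colMeans(pts)   # (row, col)
  bp <- which(band, arr.ind = TRUE)
  ry <- bp[, 1] - cc[1]; rx <- bp[, 2] - cc[2]
  nr <- sqrt(rx^2 + ry^2)
  keep <- nr > 1e-9
  v <- flowVectors(acc)
  vx <- v[, , 1][band]; vy <- v[, , 2][band]
  mean((vx[keep] * rx[keep] + vy[keep] * ry[keep]) / nr[keep])
}
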