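# Geometric fixtures and independent oracle implementations used across the
# suite. Oracles are deliberately written as plain, direct computations,
# separate from the package's code paths.

# ---- fixtures --------------------------------------------------------------

diskMask <- function(h = 128, w = 128, center = c(64.5, 64.5), r = 50) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  matrix((g$r - center[1])^2 + (g$c - center[2])^2 <= r^2, h, w)
}

ellipseMask <- function(h = 220, w = 220, center = c(110.5, 110.5),
                        a = 80, b = 40, theta = 0) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  dx <- g$c - center[2]; dy <- g$r - center[1]
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  matrix((xr / a)^2 + (yr / b)^2 <= 1, h, w)
}

# star-shaped polygon mask from a polar radius function (exact rasterization)
polarMask <- function(h, w, center, radiusFun) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  dx <- g$c - center[2]; dy <- g$r - center[1]
  phi <- atan2(dy, dx)
  matrix(sqrt(dx^2 + dy^2) <= radiusFun(phi), h, w)
}

starMask <- function(h = 128, w = 128, center = c(64.5, 64.5),
                     rOuter = 50, rInner = 22, points = 5) {
  polarMask(h, w, center, function(phi) {
    m <- (rOuter + rInner) / 2; amp <- (rOuter - rInner) / 2
    m + amp * cos(points * phi)
  })
}

# step-edge disk image: constant inside/outside intensities
stepDiskImage <- function(h = 128, w = 128, center = c(64.5, 64.5), r = 50,
                          inside = 0, outside = 255) {
  m <- diskMask(h, w, center, r)
  img <- array(outside, dim = c(h, w, 3))
  for (ch in 1:3) { p <- img[, , ch]; p[m] <- inside; img[, , ch] <- p }
  img
}

# flat image of a constant sRGB color
flatImage <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# integer-pixel translation with edge replication
translateImage <- function(img, dr, dc) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  img[ri, ci, , drop = FALSE]
}

# textured lesion frame for flow tests (strong texture, low noise; the
# structural seed is shared so frames depict the same lesion, while the
# pixel noise is redrawn per frame as in any real acquisition)
flowLesion <- function(center = c(80, 80), radius = 35, seed = 5,
                       canvas = c(160, 160)) {
  generateLesion(lesionSpec(canvas = canvas, center = center,
                            radius = radius, textureAmp = 0.3,
                            noiseSigma = 0.005, seed = seed),
                 noiseSeed = 7 + round(97 * center[2]) + round(31 * radius))
}

# ---- oracles ---------------------------------------------------------------

# Pixel count inside (or on) a polygon by crossing-number ray casting with an
# explicit on-edge test; independent of the package's half-plane counting.
oraclePolygonPixelCount <- function(polyXY, h, w) {
  nv <- nrow(polyXY)
  g <- expand.grid(py = seq_len(h), px = seq_len(w))
  px <- g$px; py <- g$py
  crossings <- integer(length(px))
  onEdge <- logical(length(px))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    x1 <- polyXY[i, 1]; y1 <- polyXY[i, 2]
    x2 <- polyXY[j, 1]; y2 <- polyXY[j, 2]
    # on-segment test via projection onto the edge
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    tpar <- if (len2 > 0)
      pmin(pmax(((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / len2, 0), 1)
    else 0
    onEdge <- onEdge |
      ((px - (x1 + tpar * (x2 - x1)))^2 +
         (py - (y1 + tpar * (y2 - y1)))^2 < 1e-18)
    # horizontal ray toward +x, half-open vertex rule
    straddles <- (y1 > py) != (y2 > py)
    xInt <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
    crossings <- crossings + as.integer(straddles & xInt > px)
  }
  sum(onEdge | crossings %% 2L == 1L)
}

oracleConvexity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  hullIdx <- grDevices::chull(pts[, 2], pts[, 1])
  poly <- cbind(pts[hullIdx, 2], pts[hullIdx, 1])
  nrow(pts) / oraclePolygonPixelCount(poly, nrow(mask), ncol(mask))
}

# Straight-line border-gradient oracle: explicit per-pixel Sobel on the
# luminance image (replicated borders), fixed normalization, contour pixels
# sampled directly.
oracleBorderGradient <- function(image, mask) {
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  h <- nrow(gray); w <- ncol(gray)
  at <- function(r, c) gray[min(max(r, 1), h), min(max(c, 1), w)]
  ct <- EBImage::ocontour(EBImage::Image(mask * 1))
  pts <- ct[[which.max(vapply(ct, nrow, integer(1)))]] + 1L
  vals <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    r <- pts[k, 1]; c <- pts[k, 2]
    gx <- (at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
      (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))
    gy <- (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1)) -
      (at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1))
    vals[k] <- sqrt(gx^2 + gy^2) / (510 * sqrt(5))
  }
  mean(vals)
}

# Closed-form product-moment correlation and its two-sided t-test p-value.
oraclePearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  rho <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# Sort-based type-7 quantile oracle.
oracleQuantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  hpos <- (n - 1) * p + 1
  lo <- floor(hpos); hi <- ceiling(hpos)
  xs[lo] + (hpos - lo) * (xs[hi] - xs[lo])
}
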