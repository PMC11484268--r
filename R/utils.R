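# Internal numeric / image helpers shared across modules.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @importFrom withr with_seed
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# BT.601 luma of an H x W x 3 array in [0, 255]; returns an H x W matrix.
.luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Shift a matrix by (dr, dc) with replicate padding at the borders.
.shiftReplicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- .clamp(seq_len(h) - dr, 1L, h)
  ci <- .clamp(seq_len(w) - dc, 1L, w)
  m[ri, ci, drop = FALSE]
}

# 2-D cross-correlation with a small kernel, replicate border, 'same' output.
# kernel[i, j] weights the sample at offset (i - cr, j - cc) from the pixel.
.correlate2d <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      k <- kernel[i, j]
      if (k != 0) out <- out + k * .shiftReplicate(m, -(i - cr), -(j - cc))
    }
  }
  out
}

# Separable cross-correlation: 1-D kernel along rows (vertical) then columns.
.sepCorrelate <- function(m, kRow, kCol) {
  h <- nrow(m); w <- ncol(m)
  cr <- (length(kRow) + 1L) %/% 2L
  cc <- (length(kCol) + 1L) %/% 2L
  tmp <- matrix(0, h, w)
  for (i in seq_along(kRow)) {
    if (kRow[i] != 0) tmp <- tmp + kRow[i] * .shiftReplicate(m, -(i - cr), 0L)
  }
  out <- matrix(0, h, w)
  for (j in seq_along(kCol)) {
    if (kCol[j] != 0) out <- out + kCol[j] * .shiftReplicate(tmp, 0L, -(j - cc))
  }
  out
}

# Box mean filter of odd size n, replicate border, via integral images.
.boxFilter <- function(m, n) {
  r <- (n - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  mp <- m[.clamp(seq(1L - r, h + r), 1L, h), .clamp(seq(1L - r, w + r), 1L, w),
          drop = FALSE]
  cs <- apply(mp, 2, cumsum)
  rs <- cs[seq(n, h + 2L * r), , drop = FALSE] -
    rbind(0, cs[seq_len(h + 2L * r - n), , drop = FALSE])
  cs2 <- t(apply(rs, 1, cumsum))
  out <- cs2[, seq(n, w + 2L * r), drop = FALSE] -
    cbind(0, cs2[, seq_len(w + 2L * r - n), drop = FALSE])
  out / (n * n)
}

# Vectorized bilinear sampling of a matrix at fractional (row, col) positions;
# positions outside the canvas are clamped to the border.
.bilinearSample <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  r <- .clamp(r, 1, h); c <- .clamp(c, 1, w)
  r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c), w - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

# Bilinear resize of a matrix to h2 x w2 (pixel-center alignment).
.resizeBilinear <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  rr <- if (h2 == 1) rep(1, 1) else 1 + (seq_len(h2) - 1) * (h - 1) / (h2 - 1)
  cc <- if (w2 == 1) rep(1, 1) else 1 + (seq_len(w2) - 1) * (w - 1) / (w2 - 1)
  grid <- expand.grid(r = rr, c = cc)
  matrix(.bilinearSample(m, grid$r, grid$c), h2, w2)
}

# Largest 8-connected component of a logical mask. EBImage::bwlabel is
# 4-connected, so 4-connected labels touching diagonally are merged first.
#' @importFrom EBImage bwlabel
.largestComponent <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nl <- max(lab)
  if (nl == 0) stop("no lesion found: mask is empty")
  if (nl > 1L) {
    parent <- seq_len(nl)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    h <- nrow(lab); w <- ncol(lab)
    for (sh in list(c(1L, 1L), c(1L, -1L))) {
      a <- lab[seq_len(h - 1L), , drop = FALSE]
      b <- lab[-1L, , drop = FALSE]
      if (sh[2] == 1L) { a <- a[, seq_len(w - 1L), drop = FALSE]; b <- b[, -1L, drop = FALSE] }
      else { a <- a[, -1L, drop = FALSE]; b <- b[, seq_len(w - 1L), drop = FALSE] }
      sel <- a > 0 & b > 0 & a != b
      if (any(sel)) {
        prs <- unique(cbind(a[sel], b[sel]))
        for (r in seq_len(nrow(prs))) {
          ra <- findRoot(prs[r, 1]); rb <- findRoot(prs[r, 2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    roots <- vapply(seq_len(nl), findRoot, integer(1))
    lab[lab > 0] <- roots[lab[lab > 0]]
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  lab == keep
}

# Quantiles of the standard t distribution are not needed; p-values are.
.pearsonP <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}
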