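# Structural similarity (SSIM) between two grayscale images, uniform
# window, computed over the region where the window fits entirely
# (no border padding enters the statistics).

.ssim <- function(a, b, win = 7L, dataRange = 255) {
  stopifnot(identical(dim(a), dim(b)))
  if (nrow(a) < win || ncol(a) < win)
    stop("images smaller than the SSIM window")
  c1 <- (0.01 * dataRange)^2
  c2 <- (0.03 * dataRange)^2
  mua <- .boxFilter(a, win); mub <- .boxFilter(b, win)
  saa <- .boxFilter(a * a, win) - mua^2
  sbb <- .boxFilter(b * b, win) - mub^2
  sab <- .boxFilter(a * b, win) - mua * mub
  ssimMap <- ((2 * mua * mub + c1) * (2 * sab + c2)) /
    ((mua^2 + mub^2 + c1) * (saa + sbb + c2))
  r <- (win - 1L) %/% 2L
  valid <- ssimMap[(r + 1):(nrow(a) - r), (r + 1):(ncol(a) - r)]
  mean(valid)
}
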