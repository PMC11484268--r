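test_that("moment ellipse recovers axes and orientation of known shapes", {
  m <- ellipseMask(a = 80, b = 40, theta = 0)
  ell <- fitLesionEllipse(m)
  expect_lt(abs(ell$majorAxisLen - 160), 2)
  expect_lt(abs(ell$minorAxisLen - 80), 2)
  expect_lt(abs(ell$orientation), 0.05)

  d <- diskMask(r = 50)
  ed <- fitLesionEllipse(d)
  expect_lt(abs(ed$majorAxisLen - 100), 2)
  expect_lt(abs(ed$minorAxisLen - 100), 2)

  m30 <- ellipseMask(a = 80, b = 40, theta = pi / 6)
  expect_lt(abs(fitLesionEllipse(m30)$orientation - pi / 6), 0.05)

  # collinear pixels are degenerate
  line <- matrix(FALSE, 32, 32); line[16, 5:28] <- TRUE
  expect_error(fitLesionEllipse(line), "collinear")
})

test_that("asymmetry is near zero for mirrored lesions and ranks warps", {
  # construct an exactly mirror-symmetric textured lesion
  fr <- generateLesion(lesionSpec(radius = 40, eccentricity = 0.4,
                                  textureAmp = 0.2, noiseSigma = 0,
                                  seed = 3))
  img <- frameImage(fr); mask <- frameMask(fr)
  for (ch in 1:3) img[81:160, , ch] <- img[80:1, , ch]
  mask[81:160, ] <- mask[80:1, ]
  for (ch in 1:3) img[, 81:160, ch] <- img[, 80:1, ch]
  mask[, 81:160] <- mask[, 80:1]
  sym <- asymmetryScore(img, mask)
  expect_lte(sym, 0.05)

  # one half replaced by uniform noise scores higher
  imgN <- img
  set.seed(4)
  noise <- array(runif(160 * 80 * 3, 0, 255), dim = c(160, 80, 3))
  imgN[, 81:160, ][mask[, 81:160]] <- noise[mask[, 81:160]]
  expect_gt(asymmetryScore(imgN, mask), sym)

  # generator warp amplitudes are ranked correctly
  mk <- function(w) generateLesion(lesionSpec(radius = 38, asymmetryWarp = w,
                                              textureAmp = 0.1, seed = 9))
  f0 <- mk(0); f4 <- mk(0.4)
  expect_gt(asymmetryScore(frameImage(f4), frameMask(f4)),
            asymmetryScore(frameImage(f0), frameMask(f0)))
})

test_that("border gradient matches the straight-line oracle and blur order", {
  # constant image has zero gradient everywhere
  flat <- flatImage(128, 128, c(120, 120, 120))
  expect_equal(borderGradientScore(flat, diskMask(r = 30)), 0)

  # hard step-edge disk equals the independent pixelwise oracle
  img <- stepDiskImage(r = 50)
  mask <- diskMask(r = 50)
  expect_equal(borderGradientScore(img, mask),
               oracleBorderGradient(img, mask), tolerance = 1e-6)

  # Gaussian blur strictly lowers the score
  blurred <- img
  for (ch in 1:3) blurred[, , ch] <- EBImage::gblur(img[, , ch], sigma = 4)
  expect_lt(borderGradientScore(blurred, mask),
            borderGradientScore(img, mask))
})

test_that("convexity is exact on closed forms and matches the hull oracle", {
  rect <- matrix(FALSE, 64, 64); rect[20:40, 15:50] <- TRUE
  expect_identical(convexityScore(rect), 1)

  expect_gte(convexityScore(diskMask(r = 50)), 0.98)

  star <- starMask()
  expect_equal(convexityScore(star), oracleConvexity(star),
               tolerance = 1e-6)
  expect_lt(convexityScore(star), 0.8)
})

test_that("diameter intersects the major axis with the contour", {
  d <- lesionDiameter(diskMask(r = 50))
  expect_equal(d$units, "px")
  expect_lt(abs(d$length - 100), 2)

  dmm <- lesionDiameter(diskMask(r = 50), mmPerPx = 0.1)
  expect_equal(dmm$units, "mm")
  expect_lt(abs(dmm$length - 10), 0.2)

  e <- lesionDiameter(ellipseMask(a = 80, b = 40))
  expect_lt(abs(e$length - 160), 3)
})

test_that("per-frame metrics stay in range and are rotation invariant", {
  set.seed(21)
  specs <- replicate(12, lesionSpec(
    radius = runif(1, 25, 42), eccentricity = runif(1, 0, 0.5),
    orientation = runif(1, -pi / 2, pi / 2),
    asymmetryWarp = runif(1, 0, 0.3), borderBlurSigma = runif(1, 0, 3),
    noiseSigma = runif(1, 0.005, 0.03), textureAmp = runif(1, 0, 0.3),
    seed = sample.int(1e6, 1)), simplify = FALSE)
  for (sp in specs) {
    fr <- generateLesion(sp)
    mv <- metricVector(fr, seed = 5)
    expect_gte(mv$asymmetry, 0); expect_lte(mv$asymmetry, 1)
    expect_gte(mv$border_gradient, 0); expect_lte(mv$border_gradient, 1)
    expect_gt(mv$convexity, 0); expect_lte(mv$convexity, 1)
    expect_gte(mv$color_dispersion, 0); expect_lte(mv$color_dispersion, 1)
    expect_gt(mv$diameter, 0)
  }

  # 90-degree rotation: transpose + reverse rows is an exact rotation
  fr <- generateLesion(lesionSpec(radius = 36, eccentricity = 0.4,
                                  asymmetryWarp = 0.25, textureAmp = 0.2,
                                  orientation = 0.3, seed = 31))
  img <- frameImage(fr); mask <- frameMask(fr)
  rot90 <- function(m) t(m[nrow(m):1, ])
  imgR <- array(0, dim = c(dim(img)[2], dim(img)[1], 3))
  for (ch in 1:3) imgR[, , ch] <- rot90(img[, , ch])
  maskR <- rot90(mask)

  expect_lt(abs(asymmetryScore(imgR, maskR) - asymmetryScore(img, mask)),
            0.03)
  expect_lt(abs(convexityScore(maskR) - convexityScore(mask)), 0.03)
  dia <- lesionDiameter(mask)$length
  expect_lt(abs(lesionDiameter(maskR)$length - dia) / dia, 0.03)
  segA <- colorSegment(img, mask, seed = 5)
  segB <- colorSegment(imgR, maskR, seed = 5)
  expect_lt(abs(colorDispersionScore(imgR, maskR, segB) -
                colorDispersionScore(img, mask, segA)), 0.03)
})

test_that("metric vectors are bitwise deterministic for a fixed seed", {
  fr <- generateLesion(lesionSpec(radius = 34, asymmetryWarp = 0.2,
                                  textureAmp = 0.25, seed = 8))
  expect_identical(metricVector(fr, seed = 17), metricVector(fr, seed = 17))
})

test_that("melanoma-like frames score higher than nevus-like frames", {
  nevus <- generateLesion(lesionSpec(radius = 32, asymmetryWarp = 0,
                                     borderBlurSigma = 0, textureAmp = 0.05,
                                     noiseSigma = 0.01, seed = 12))
  melanoma <- generateLesion(lesionSpec(
    radius = 36, asymmetryWarp = 0.4, borderBlurSigma = 0.5,
    palette = list(colors = matrix(c(0.46, 0.17, 0.10,
                                     0.24, 0.26, 0.18,
                                     0.16, 0.18, 0.26), 3, 3, byrow = TRUE),
                   fractions = c(0.4, 0.4, 0.2)),
    textureAmp = 0.3, noiseSigma = 0.03, seed = 12))
  mvN <- metricVector(nevus, seed = 3)
  mvM <- metricVector(melanoma, seed = 3)
  expect_gt(mvM$asymmetry, mvN$asymmetry)
  expect_gt(mvM$color_dispersion, mvN$color_dispersion)
})
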