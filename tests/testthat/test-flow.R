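test_that("optical flow recovers constructed motion", {
  f1 <- flowLesion(center = c(80, 78))
  f2 <- flowLesion(center = c(80, 81))   # content moved +3 columns
  mask <- frameMask(f1)

  # identical frames: essentially no motion
  fl0 <- farnebackFlow(f1, f1)
  mag0 <- sqrt(fl0[, , 1]^2 + fl0[, , 2]^2)
  expect_lt(quantile(mag0, 0.99), 0.1)

  # (3, 0) translation recovered over the lesion within 0.5 px
  fl <- farnebackFlow(f1, f2)
  expect_lt(abs(mean(fl[, , 1][mask]) - 3), 0.5)
  expect_lt(abs(mean(fl[, , 2][mask])), 0.5)

  # dimension mismatch
  small <- generateLesion(lesionSpec(canvas = c(96, 96), radius = 25,
                                     seed = 5))
  expect_error(farnebackFlow(f1, small), "dimensions")
})

test_that("accumulation sums pairwise flows with directional cancellation", {
  fA <- flowLesion(center = c(80, 77))
  fB <- flowLesion(center = c(80, 79))
  fC <- flowLesion(center = c(80, 81))
  mask <- frameMask(fA)

  seq3 <- FrameSequence(list(fA, fB, fC))
  acc <- accumulateFlow(seq3)
  expect_s4_class(acc, "AccumulatedFlow")

  # linearity: the accumulated field is exactly the sum of pair flows
  manual <- farnebackFlow(fA, fB) + farnebackFlow(fB, fC)
  expect_identical(flowVectors(acc), manual)
  # magnitude is consistent with the vectors by construction
  expect_lt(max(abs(flowMagnitude(acc) -
                    sqrt(manual[, , 1]^2 + manual[, , 2]^2))), 1e-12)

  # two +2 steps accumulate to ~+4 over pixels inside the lesion throughout
  core <- frameMask(fA) & frameMask(fC)
  expect_lt(abs(mean(flowVectors(acc)[, , 1][core]) - 4), 1)

  # opposite translations cancel (direction information is lost by design)
  seqCancel <- FrameSequence(list(fA, fC, fA))
  accC <- accumulateFlow(seqCancel)
  expect_lt(mean(flowMagnitude(accC)[mask]), 1)

  # static sequence: flat magnitude
  seqStatic <- FrameSequence(list(fA, fA, fA))
  expect_lt(quantile(flowMagnitude(accumulateFlow(seqStatic)), 0.99), 0.2)
})

test_that("heatmap rendering is pure and localizes hot regions", {
  v <- array(0, dim = c(64, 64, 2))
  acc0 <- lesionflow:::.AccumulatedFlow(v)

  # zero flow renders the lowest colormap color everywhere
  hm0 <- flowHeatmap(acc0)
  expect_equal(dim(hm0), c(64, 64, 3))
  expect_true(all(hm0[, , 1] == hm0[1, 1, 1]))
  expect_equal(as.numeric(hm0[1, 1, ]), c(0, 0, 255))

  # a single hot region carries the red end of the map
  v[25:34, 40:49, 1] <- 5
  accH <- lesionflow:::.AccumulatedFlow(v)
  before <- flowVectors(accH)
  hm <- flowHeatmap(accH)
  idx <- which(hm[, , 1] == max(hm[, , 1]), arr.ind = TRUE)
  expect_true(all(idx[, 1] >= 25 & idx[, 1] <= 34))
  expect_true(all(idx[, 2] >= 40 & idx[, 2] <= 49))
  # rendering does not alter the flow object
  expect_identical(flowVectors(accH), before)

  # overlay keeps the context image dimensions; quiver draws on top
  ctx <- flatImage(64, 64, c(100, 100, 100))
  ov <- flowHeatmap(accH, overlayOn = ctx, alpha = 0.5, quiver = TRUE)
  expect_equal(dim(ov), dim(ctx))
  expect_error(flowHeatmap(accH, overlayOn = flatImage(32, 32, c(0, 0, 0))),
               "dimensions")
})

test_that("radial expansion statistic signs expansion and contraction", {
  grow1 <- flowLesion(center = c(80, 80), radius = 33)
  grow2 <- flowLesion(center = c(80, 80), radius = 37)
  mask <- frameMask(grow1)

  accG <- accumulateFlow(FrameSequence(list(grow1, grow2)))
  expect_gt(radialExpansionStat(accG, mask), 0)

  accS <- accumulateFlow(FrameSequence(list(grow2, grow1)))
  expect_lt(radialExpansionStat(accS, frameMask(grow2)), 0)

  # rigid translation: radial components cancel around the boundary
  t1 <- flowLesion(center = c(80, 78))
  t2 <- flowLesion(center = c(80, 81))
  accT <- accumulateFlow(FrameSequence(list(t1, t2)))
  expect_lt(abs(radialExpansionStat(accT, frameMask(t1))), 0.1 * 3)
})
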