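test_that("sequences load from disk with deterministic ordering and checks", {
  dir <- withr::local_tempdir()
  fr <- generateLesion(lesionSpec(canvas = c(64, 64), radius = 18, seed = 1))
  for (i in 0:3)
    writeLesionImage(frameImage(fr), file.path(dir, sprintf("f%03d.png", i)))

  seq <- loadSequence(dir)
  expect_s4_class(seq, "FrameSequence")
  expect_length(seq, 4L)
  # masks were auto-segmented
  expect_gt(sum(frameMask(seq[[1]])), 100)

  # frame ordering is the lexicographic filename sort, reproducibly
  seq2 <- loadSequence(rev(list.files(dir, full.names = TRUE)))
  expect_identical(frameImage(seq2[[4]]), frameImage(seq[[4]]))

  # dimension mismatch names the offending file
  small <- generateLesion(lesionSpec(canvas = c(48, 48), radius = 12,
                                     seed = 1))
  writeLesionImage(frameImage(small), file.path(dir, "f004.png"))
  expect_error(loadSequence(dir), "f004")

  # fewer than two frames is an error
  expect_error(loadSequence(list.files(dir, full.names = TRUE)[1]),
               "at least 2")
})

test_that("multi-channel mask files are coerced with a warning", {
  dir <- withr::local_tempdir()
  fr <- generateLesion(lesionSpec(canvas = c(64, 64), radius = 18, seed = 2))
  for (i in 0:1)
    writeLesionImage(frameImage(fr), file.path(dir, sprintf("f%03d.png", i)))
  # write the mask as a 3-channel image
  m3 <- array(rep(frameMask(fr) * 255, 3), dim = c(64, 64, 3))
  maskPaths <- file.path(dir, c("f000_m.png", "f001_m.png"))
  for (p in maskPaths) writeLesionImage(m3, p)

  w <- testthat::capture_warnings(
    seq <- loadSequence(file.path(dir, c("f000.png", "f001.png")),
                        maskFiles = maskPaths))
  expect_match(w, "thresholding", all = TRUE)
  expect_length(w, 2L)
  expect_identical(frameMask(seq[[1]]), frameMask(fr))
})

test_that("mask PNG round-trips exactly", {
  dir <- withr::local_tempdir()
  m <- diskMask(64, 64, c(32.5, 32.5), 20)
  p <- file.path(dir, "m.png")
  writeMaskImage(m, p)
  m2 <- lesionflow:::.readMaskArray(p)
  expect_identical(m2, m)
})

test_that("metric tables round-trip through CSV to 1e-6", {
  traj <- data.frame(
    frame_index = 0:2,
    asymmetry = c(0.12345678, 0.23456789, 0.3456789),
    border_gradient = c(0.01234567, 0.02345678, 0.0345678),
    convexity = c(0.99876543, 0.98765432, 0.9765432),
    color_dispersion = c(0.00123456, 0.01234567, 0.1234567),
    diameter = c(100.123456, 105.234567, 110.345678),
    diameter_units = "px",
    color_evolution_from_first = c(0, 0.04567891, 0.0987654))
  path <- withr::local_tempfile(fileext = ".csv")
  writeMetrics(traj, path)
  back <- readMetrics(path)
  expect_equal(nrow(back), 3L)
  for (col in setdiff(names(traj), "diameter_units"))
    expect_equal(back[[col]], traj[[col]], tolerance = 1e-6)

  expect_error(writeMetrics(traj[0, ], path), "non-empty")
})

test_that("confidence series round-trip and are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  conf <- c(0.97, 0.8, 0.45, 0.1)
  writeConfidence(conf, path)
  expect_equal(readConfidence(path), conf, tolerance = 1e-9)
  writeLines("confidence_nevus\n1.4", path)
  expect_error(readConfidence(path), "0, 1")
})

test_that("domain objects enforce their invariants", {
  img <- array(128, dim = c(32, 32, 3))
  expect_error(LesionFrame(array(128, dim = c(8, 32, 3)),
                           mask = matrix(TRUE, 8, 32)), "16")
  expect_error(LesionFrame(img, mask = matrix(TRUE, 16, 32)), "dimensions")
  expect_error(LesionFrame(img, mask = matrix(TRUE, 32, 32), mmPerPx = -1),
               "positive")
  fr <- LesionFrame(img, mask = diskMask(32, 32, c(16, 16), 8),
                    mmPerPx = 0.1)
  expect_equal(mmPerPx(fr), 0.1)
  expect_error(FrameSequence(list(fr, LesionFrame(
    array(128, dim = c(48, 48, 3)), mask = matrix(TRUE, 48, 48)))),
    "same dimensions")
})
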