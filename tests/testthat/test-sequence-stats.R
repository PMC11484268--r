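test_that("trajectories are constant on static sequences and deterministic", {
  fr <- generateLesion(lesionSpec(canvas = c(128, 128), radius = 30,
                                  textureAmp = 0.15, seed = 4))
  seqS <- FrameSequence(rep(list(fr), 5))
  traj <- computeTrajectories(seqS, seed = 3)
  expect_equal(nrow(traj), 5L)
  expect_equal(traj$frame_index, 0:4)
  for (m in c("asymmetry", "border_gradient", "convexity",
              "color_dispersion", "diameter")) {
    expect_lt(max(traj[[m]]) - min(traj[[m]]), 1e-6)
  }
  expect_true(all(traj$color_evolution_from_first <= 0.01))
  expect_equal(traj$color_evolution_from_first[1], 0)

  # bitwise determinism
  expect_identical(computeTrajectories(seqS, seed = 3), traj)
})

test_that("diameter trajectories track linear generator growth", {
  start <- lesionSpec(canvas = c(192, 192), radius = 25, textureAmp = 0.15,
                      seed = 5)
  end <- lesionSpec(canvas = c(192, 192), radius = 37.5, textureAmp = 0.15,
                    seed = 5)
  res <- generateProgression(progressionSpec(10, start, end))
  traj <- computeTrajectories(res$sequence, seed = 2)
  fit <- stats::lm(diameter ~ frame_index, data = traj)
  trueSlope <- (75 - 50) / 9
  expect_lt(abs(coef(fit)[2] - trueSlope) / trueSlope, 0.1)
})

test_that("first-vs-last deltas follow their definition", {
  traj <- data.frame(frame_index = 0:2,
                     asymmetry = c(0.30, 0.40, 0.489),
                     border_gradient = c(0.2, 0.2, 0.2),
                     convexity = c(1, 1, 1),
                     color_dispersion = c(0, 0, 0.05),
                     diameter = c(100, 101, 102))
  d <- firstLastDelta(traj)
  expect_equal(d$delta[d$metric == "diameter"], 2)
  expect_lt(abs(d$delta[d$metric == "asymmetry"] - 63), 0.5)
  expect_equal(d$delta[d$metric == "border_gradient"], 0)
  # near-zero baseline switches to the absolute difference, flagged
  expect_equal(d$type[d$metric == "color_dispersion"], "absolute")
  expect_equal(d$delta[d$metric == "color_dispersion"], 0.05)

  # reversal identity: delta_rev = -delta * first/last for positive metrics
  trajRev <- traj[3:1, ]
  dRev <- firstLastDelta(trajRev)
  a <- d[d$metric == "asymmetry", ]
  aR <- dRev[dRev$metric == "asymmetry", ]
  expect_equal(aR$delta, -a$delta * a$first / a$last, tolerance = 1e-12)
})

test_that("confidence correlation matches the closed-form oracle", {
  traj <- data.frame(frame_index = 0:4,
                     asymmetry = c(1, 2, 3, 4, 5) / 10,
                     border_gradient = c(2, 1, 4, 3, 6) / 10,
                     convexity = rep(0.9, 5),
                     color_dispersion = c(0.1, 0.3, 0.2, 0.5, 0.4),
                     diameter = 100:104)
  conf <- c(0.9, 0.8, 0.6, 0.5, 0.2)

  out <- correlateWithConfidence(traj, conf)
  for (m in c("asymmetry", "border_gradient", "color_dispersion",
              "diameter")) {
    o <- oraclePearson(traj[[m]], conf)
    expect_equal(out$rho[out$metric == m], o$rho, tolerance = 1e-9)
    expect_equal(out$p_value[out$metric == m], o$p, tolerance = 1e-9)
  }

  # exact correlation with itself and its negation
  trajId <- traj; trajId$asymmetry <- conf
  expect_equal(correlateWithConfidence(trajId, conf)$rho[1], 1)
  trajNeg <- traj; trajNeg$asymmetry <- 1 - conf
  expect_equal(correlateWithConfidence(trajNeg, conf)$rho[1], -1)

  # constant series: undefined, reported as NA (not 0)
  expect_true(is.na(out$rho[out$metric == "convexity"]))

  # symmetry under exchanging the roles of the two series
  x <- traj$border_gradient; y <- conf
  t1 <- data.frame(frame_index = 0:4, asymmetry = x,
                   border_gradient = x, convexity = x,
                   color_dispersion = x, diameter = x)
  t2 <- t1; t2[, -1] <- y
  expect_equal(correlateWithConfidence(t1, y)$rho[1],
               correlateWithConfidence(t2, x)$rho[1], tolerance = 1e-12)

  # mismatched lengths error; BH adjustment is monotone non-decreasing
  expect_error(correlateWithConfidence(traj, conf[-1]), "length")
  raw <- correlateWithConfidence(traj, conf)
  bh <- correlateWithConfidence(traj, conf, pAdjust = "BH")
  ok <- !is.na(raw$p_value)
  expect_true(all(bh$p_value[ok] >= raw$p_value[ok] - 1e-15))
})

test_that("distribution summaries match a sort-based quantile oracle", {
  traj <- data.frame(frame_index = 0:99,
                     asymmetry = rep(0.3, 100),
                     border_gradient = (1:100) / 100,
                     convexity = rep(1, 100),
                     color_dispersion = stats::runif(100),
                     diameter = stats::rnorm(100, 100, 5))
  s <- distributionSummary(traj)

  # constant series collapses to a single value with zero IQR
  a <- s[s$metric == "asymmetry", ]
  expect_true(all(abs(unlist(a[, c("min", "q1", "median", "q3", "max")]) -
                      0.3) < 1e-12))
  expect_equal(a$iqr, 0)

  # series 1..100 (scaled): median 50.5, IQR 49.5
  b <- s[s$metric == "border_gradient", ]
  expect_equal(b$median * 100, 50.5)
  expect_equal(b$iqr * 100, 49.5)

  # random series against the oracle at 1e-9
  for (m in c("color_dispersion", "diameter")) {
    row <- s[s$metric == m, ]
    x <- traj[[m]]
    expect_equal(row$q1, oracleQuantile(x, 0.25), tolerance = 1e-9)
    expect_equal(row$median, oracleQuantile(x, 0.5), tolerance = 1e-9)
    expect_equal(row$q3, oracleQuantile(x, 0.75), tolerance = 1e-9)
  }
})
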