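test_that("adaptive segmentation respects contrast and polarity", {
  expect_equal(sum(segmentNetwork(matrix(128, 100, 100))), 0)
  expect_error(segmentNetwork(matrix(0, 50, 50), window = 70), "odd")

  # dark disc on bright agar: count within 3% of the drawn disc
  g <- makeGrowingDiskSeries(dim = c(120, 120), r0 = 20, k = 0,
                             n_frames = 1, antialias = FALSE)
  m <- segmentNetwork(g$series[[1]], window = 71, offset = 4)
  expect_lt(abs(sum(m) - g$truth$area_px[1]) / g$truth$area_px[1], 0.03)

  # inverted polarity: bright veins are never foreground in inverse mode
  v <- makeVeinNetwork(fg = 240, bg = 100, seed = 1)
  minv <- segmentNetwork(v$frame, window = 79, offset = 2)
  expect_equal(sum(minv[v$frame > 200]), 0)
})

test_that("area series converts pixel counts and subtracts the baseline", {
  m <- matrix(FALSE, 120, 120)
  m[1:100, 1:100] <- TRUE                     # 10000 px
  cal10 <- calibrateScale(1000, 10)           # 10 um/px
  a <- areaSeries(list(m, m, m), cal10, c(0, 60, 120))
  expect_equal(a@areaMm2, rep(1.0, 3))
  expect_equal(a@areaNormMm2, rep(0, 3))
  expect_error(areaSeries(list(), cal10, numeric()), "empty")
})

test_that("growing-disc phantom area matches the analytic oracle", {
  g <- makeGrowingDiskSeries(dim = c(120, 120), r0 = 15, k = 0.26,
                             n_frames = 25, antialias = FALSE)
  masks <- lapply(frames(g$series), segmentNetwork, window = 71, offset = 4)
  a <- areaSeries(masks, cal100, timestamps(g$series))
  expect_true(all(abs(a@areaMm2 - g$truth$area_mm2) / g$truth$area_mm2
                  < 0.03))
})

test_that("growth rate follows its defining ratio", {
  s <- new("AreaSeries", timesH = c(0, 12, 24), areaMm2 = c(50, 80, 50),
           areaNormMm2 = c(0, 30, 0), condition = "x")
  expect_equal(growthRate(s), 0)
  s@areaMm2 <- c(50, 80, 100)
  expect_equal(growthRate(s), 1)
  # scale invariance
  s2 <- s; s2@areaMm2 <- s@areaMm2 * 7.3; s2@areaNormMm2 <- s2@areaMm2 - s2@areaMm2[1]
  expect_equal(growthRate(s2), growthRate(s))
  # degenerate cases
  s@areaMm2 <- c(0, 1, 2); s@areaNormMm2 <- c(0, 1, 2)
  expect_error(growthRate(s), "undefined")
  short <- new("AreaSeries", timesH = c(0, 6), areaMm2 = c(1, 2),
               areaNormMm2 = c(0, 1), condition = "x")
  expect_error(growthRate(short), "required")
})

test_that("exploration accumulates the union of occupied pixels", {
  m1 <- matrix(FALSE, 50, 50); m1[10:20, 10:20] <- TRUE
  m2 <- matrix(FALSE, 50, 50); m2[30:40, 30:40] <- TRUE
  cal10 <- calibrateScale(1000, 10)
  # static organism: explored equals area at every t
  e <- explorationSeries(list(m1, m1, m1), cal10, c(0, 60, 120))
  a <- areaSeries(list(m1, m1, m1), cal10, c(0, 60, 120))
  expect_equal(e@exploredMm2, a@areaMm2)
  # shrinking organism: explored stays at its maximum
  sub <- m1; sub[10:15, ] <- FALSE
  e2 <- explorationSeries(list(m1, sub, sub), cal10, c(0, 60, 120))
  expect_equal(e2@exploredMm2, rep(e2@exploredMm2[1], 3))
  # disjoint translation doubles the union
  e3 <- explorationSeries(list(m1, m2), cal10, c(0, 60))
  expect_equal(e3@exploredMm2[2], 2 * e3@exploredMm2[1])
})

test_that("exploration is monotone for arbitrary mask sequences", {
  set.seed(31)
  for (rep in 1:5) {
    masks <- lapply(1:8, function(i) matrix(runif(400) < 0.3, 20, 20))
    e <- explorationSeries(masks, cal100, (0:7) * 60)
    expect_true(all(diff(e@exploredMm2) >= -1e-12))
    # explored always dominates instantaneous area
    a <- areaSeries(masks, cal100, (0:7) * 60)
    expect_true(all(e@exploredMm2 >= a@areaMm2 - 1e-12))
  }
})

test_that("translating-disc phantom exploration matches the union oracle", {
  tr <- makeGrowingDiskSeries(dim = c(80, 260), r0 = 14, mode = "translate",
                              center0 = c(40, 25), step_px = c(0, 28),
                              n_frames = 8, interval_s = 3 * 3600,
                              antialias = FALSE)
  masks <- lapply(frames(tr$series), segmentNetwork, window = 71,
                  offset = 4)
  e <- explorationSeries(masks, cal100, timestamps(tr$series))
  # discs displaced by their own diameter: union = 8 disjoint discs
  oracle <- 8 * tr$truth$area_px[1] * (100 / 1000)^2
  expect_lt(abs(e@exploredMm2[8] - oracle) / oracle, 0.03)
  expect_equal(explorationRate(e, 21), e@exploredMm2[8] / 21)
})

test_that("area and exploration ignore padding outside the dish", {
  m <- matrix(FALSE, 60, 60); m[20:30, 20:30] <- TRUE
  pad <- matrix(FALSE, 100, 100); pad[21:80, 21:80] <- m
  a1 <- areaSeries(list(m), cal100, 0)
  a2 <- areaSeries(list(pad), cal100, 0)
  expect_equal(a1@areaMm2, a2@areaMm2)
})

test_that("growth inhibition is the normalised difference to control", {
  expect_equal(growthInhibition(75, 100), -0.25)
  expect_equal(growthInhibition(100, 100), 0)
  expect_equal(growthInhibition(80, c(90, 110)), -0.20)
  expect_error(growthInhibition(50, 0), "positive")
})

test_that("dose-response polynomial fitting recovers known curves", {
  x <- c(0, 10, 20, 40, 60, 80)
  fit <- fitDoseResponse(x, x^3)
  expect_equal(fit$coefficients, c(1, 0, 0, 0), tolerance = 1e-8)

  fitc <- fitDoseResponse(x, rep(0.2, 6))
  expect_equal(fitc$coefficients, c(0, 0, 0, 0.2), tolerance = 1e-8)

  # statistical recovery: the leading coefficient sits within 2 standard
  # errors of truth for the vast majority of noise draws
  truth <- c(2e-6, -1e-4, 3e-3, 0.05)
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    y <- truth[1] * x^3 + truth[2] * x^2 + truth[3] * x + truth[4] +
      rnorm(6, 0, 0.02)
    fitn <- fitDoseResponse(x, y)
    se <- summary(fitn$fit)$coefficients[4, 2]
    hits <- hits + (abs(fitn$coefficients[1] - truth[1]) < 2 * se)
  }
  expect_gte(hits, 16L)

  expect_error(fitDoseResponse(c(0, 1, 2), c(1, 2, 3)), "distinct")
})
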