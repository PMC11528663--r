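sinTrace <- function(f, n = 900, fs = 0.25, a = 1, phi = 0)
  a * sin(2 * pi * f * (0:(n - 1)) / fs + phi)

test_that("the IQR noise gate removes noise and preserves signal and DC", {
  set.seed(71)
  x <- sinTrace(0.010)
  noisy <- x + rnorm(900, 0, 0.45)
  den <- iqrNoiseFilter(noisy)
  expect_length(den, 900)
  expect_true(is.numeric(den) && all(is.finite(den)))
  expect_gt(cor(den, x), cor(noisy, x))

  # pure sinusoid passes essentially unchanged
  den2 <- iqrNoiseFilter(x)
  expect_lt(max(abs(den2 - x)), 0.01)

  # constant trace: DC preserved exactly
  expect_equal(iqrNoiseFilter(rep(5, 64)), rep(5, 64), tolerance = 1e-12)

  expect_error(iqrNoiseFilter(1:10), "16 samples")
  expect_error(iqrNoiseFilter(rnorm(64), times_s = cumsum(runif(64))),
               "uniformly")
})

test_that("Welch slicing follows the stride formula", {
  w <- welchPsd(rnorm(900), 256, 0.9)
  expect_equal(w$stride, 25L)
  expect_equal(w$n_slices, 26L)

  # property: floor((L - seg)/stride) + 1 over random valid configs
  set.seed(72)
  for (i in 1:10) {
    L <- sample(300:1200, 1)
    seg <- sample(64:256, 1)
    ov <- runif(1, 0, 0.95)
    w <- welchPsd(rnorm(L), seg, ov)
    stride <- max(1L, floor(seg * (1 - ov)))
    expect_equal(w$n_slices, floor((L - seg) / stride) + 1L)
  }

  # edge cases
  expect_equal(welchPsd(rnorm(512), 256, 0)$stride, 256L)
  expect_equal(welchPsd(rnorm(256), 256, 0.9)$n_slices, 1L)
  expect_error(welchPsd(rnorm(100), 256), "exceeds")
})

test_that("the weighted slice estimator resolves sub-bin frequencies", {
  p <- numeric(256); p[11] <- 1   # all power in bin i = 10
  expect_equal(estimateSliceFrequency(p, 0.25, 256), 10 * 0.25 / 256)

  # symmetric power about j gives exactly j Fs/N
  p2 <- numeric(256); p2[9:13] <- c(1, 2, 5, 2, 1)
  expect_equal(estimateSliceFrequency(p2, 0.25, 256), 10 * 0.25 / 256)

  expect_error(estimateSliceFrequency(numeric(256), 0.25, 256), "all-zero")

  # Hanning-windowed sinusoid off bin centre: within 0.001 Hz
  x <- sinTrace(0.010, n = 256)
  w <- welchPsd(x, 256, 0)
  est <- estimateSliceFrequency(w$power[, 1], 0.25, 256)
  expect_lt(abs(est - 0.010), 0.001)
})

test_that("contraction frequency recovers stationary and drifting rhythms", {
  est <- contractionFrequency(sinTrace(0.012) + rnorm(900, 0, 0.2))
  expect_lt(abs(estFrequency(est) - 0.012), 0.001)
  expect_false(est@lowConfidence)
  expect_lt(estFrequency(est), 0.25 / 2)   # Nyquist

  # linear chirp: Welch average lands near the midpoint
  ch <- makePulsatingSeries(dim = c(40, 60), n_frames = 900,
                            freq_hz = c(0.008, 0.016), seed = 73)
  est2 <- contractionFrequency(ch$truth$width_px)
  expect_lt(abs(estFrequency(est2) - 0.012), 0.002)

  # featureless noise is flagged low-confidence
  set.seed(74)
  est3 <- contractionFrequency(rnorm(900))
  expect_true(est3@lowConfidence)
})

test_that("estimates always respect the Nyquist bound", {
  set.seed(75)
  for (f in c(0.005, 0.02, 0.05, 0.1)) {
    e <- contractionFrequency(sinTrace(f) + rnorm(900, 0, 0.1))
    expect_gt(estFrequency(e), 0)
    expect_lt(estFrequency(e), 0.125)
  }
})

test_that("organism averaging excludes 1.5 IQR outlier sections", {
  out <- organismAverage(c(10, 10, 10, 30) / 1000)
  expect_equal(out$mean_hz, 0.010)
  expect_equal(out$excluded, "4")
  expect_equal(out$n_used, 3L)

  same <- organismAverage(rep(0.012, 5))
  expect_equal(same$sd_hz, 0)
  expect_length(same$excluded, 0)

  expect_warning(two <- organismAverage(c(0.01, 0.02)), "fewer than 3")
  expect_equal(two$mean_hz, 0.015)
})

test_that("a multi-vein phantom averages to the driving frequency", {
  p <- makePulsatingSeries(dim = c(220, 120), n_veins = 8, n_frames = 900,
                           freq_hz = 0.010, phase = NULL, noise_sd = 0,
                           seed = 76)
  tw <- p$truth
  est <- lapply(split(tw, tw$vein), function(d)
    contractionFrequency(d$width_px, section_id = as.character(d$vein[1])))
  org <- organismAverage(est)
  expect_lt(abs(org$mean_hz - 0.010), 0.001)
})
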