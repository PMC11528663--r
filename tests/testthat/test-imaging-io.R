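test_that("frame series loading orders, times and validates frames", {
  dir <- withr::local_tempdir()
  f <- matrix(150, 40, 40)
  paths <- file.path(dir, sprintf("f%02d.png", 1:3))
  for (p in paths) png::writePNG(f / 255, p)
  fs <- loadFrameSeries(paths, interval_s = 60)
  expect_equal(timestamps(fs), c(0, 60, 120))
  expect_equal(nFrames(fs), 3L)
  expect_equal(dim(fs[[1]]), c(40, 40))

  # dimension mismatch is a validation error naming the offender
  bad <- file.path(dir, "g.png")
  png::writePNG(matrix(0.5, 20, 20), bad)
  expect_error(loadFrameSeries(c(paths, bad)), "dimension mismatch")
  expect_error(loadFrameSeries(file.path(dir, "missing.png")), "missing.png")

  # manifest with explicit times overrides index arithmetic
  man <- data.frame(path = rev(paths), t_seconds = c(240, 120, 0))
  fs2 <- loadFrameSeries(manifest = man)
  expect_equal(timestamps(fs2), c(0, 120, 240))
})

test_that("RGB input is converted by luminance weighting", {
  dir <- withr::local_tempdir()
  arr <- array(0, dim = c(16, 16, 3))
  arr[, , 1] <- 0.8; arr[, , 2] <- 0.4; arr[, , 3] <- 0.2
  p <- file.path(dir, "rgb.png")
  png::writePNG(arr, p)
  g <- readGreyFrame(p)
  expect_equal(dim(g), c(16, 16))
  # independent oracle: channel-weighted mean on the stored 8-bit values
  want <- 0.299 * round(0.8 * 255) + 0.587 * round(0.4 * 255) +
    0.114 * round(0.2 * 255)
  expect_equal(unique(as.vector(g)), want, tolerance = 1e-6)
})

test_that("non-local-means denoising reduces noise and preserves structure", {
  flat <- matrix(180, 60, 60)
  expect_equal(denoiseFrame(flat), flat, tolerance = 1e-8)

  set.seed(11)
  noisy <- pmin(pmax(flat + rnorm(3600, 0, 10), 0), 255)
  den <- denoiseFrame(noisy)
  expect_lt(sd(den), sd(noisy))
  expect_equal(dim(den), dim(noisy))
  expect_true(all(den >= 0 & den <= 255))

  # strength zero is the null filter; even template window is rejected
  expect_identical(denoiseFrame(noisy, strength = 0), noisy)
  expect_error(denoiseFrame(noisy, template_window = 4), "odd")

  # second pass changes the mean intensity less than the first
  den2 <- denoiseFrame(den)
  expect_lt(abs(mean(den2) - mean(den)), abs(mean(den) - mean(noisy)))
})

test_that("scale calibration is exact and round-trips", {
  expect_equal(pixelPitch(calibrateScale(1000, 10)), 10)
  # 92 mm dish diameter spanning 3300 px
  expect_equal(pixelPitch(calibrateScale(3300, 92)), 27.8787878787879,
               tolerance = 1e-10)
  expect_error(calibrateScale(0, 10), "positive")
  expect_error(calibrateScale(100, -1), "positive")
  # px -> mm -> px identity
  cal <- calibrateScale(1234, 92)
  px <- 517
  mm <- px * pixelPitch(cal) / 1000
  expect_equal(mm * 1000 / pixelPitch(cal), px, tolerance = 1e-12)
})

test_that("dish ROI detection recovers seeded phantom rims", {
  set.seed(21)
  for (i in 1:8) {
    r <- runif(1, 70, 95)
    ctr <- c(runif(1, r + 12, 228 - r), runif(1, r + 12, 228 - r))
    d <- makeDish(dim = c(240, 240), center = ctr, radius = r,
                  noise_sd = 3, seed = i)
    roi <- detectDishROI(d$frame, 60, 105)
    expect_lt(sqrt(sum((roi@center - ctr)^2)), 5)
    expect_lt(abs(roi@radius - r) / r, 0.02)
  }
})

test_that("ROI detection fails cleanly without a qualifying rim", {
  expect_error(detectDishROI(matrix(128, 120, 120), 40, 60), "manual ROI")
  # rim outside the admissible radius bounds is rejected
  d <- makeDish(dim = c(200, 200), radius = 60, seed = 1)
  expect_error(detectDishROI(d$frame, 80, 95), "manual ROI")
})

test_that("applying an ROI masks only the exterior", {
  d <- makeDish(dim = c(120, 120), radius = 45)
  roi_all <- roiMask(c(60.5, 60.5), 200, c(120, 120))
  expect_identical(applyROI(d$frame, roi_all), d$frame)

  roi_none <- roiMask(c(-500, -500), 1, c(120, 120))
  expect_true(all(applyROI(d$frame, roi_none) == 255))

  roi <- roiMask(c(60.5, 60.5), 30, c(120, 120))
  out <- applyROI(d$frame, roi, fill = 7)
  expect_identical(out[roi@mask], d$frame[roi@mask])
  expect_equal(sum(out[!roi@mask]), 7 * sum(!roi@mask))
  expect_error(applyROI(matrix(0, 10, 10), roi), "dimensions differ")
})
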