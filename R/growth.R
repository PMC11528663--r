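#' Adaptive-threshold segmentation of the organism
#'
#' Segments the dark plasmodial network from the bright agar background with
#' Gaussian-weighted local-mean thresholding in inverse-binary mode: a pixel
#' is foreground iff its intensity is below the local weighted mean minus the
#' offset. This is robust to the uneven illumination typical of dish
#' recordings. Defaults are the growth-regime parameters (71 px window,
#' offset 4); the vein regime uses a 69-91 px window with offset 2.
#'
#' @param frame denoised, masked greyscale matrix.
#' @param window odd neighbourhood size in pixels (default 71).
#' @param offset constant subtracted from the local mean (default 4).
#' @param roi optional \linkS4class{ROIMask}; foreground is restricted to it.
#' @return logical matrix, `TRUE` on the organism.
#' @export
segmentNetwork <- function(frame, window = 71, offset = 4, roi = NULL) {
  stopifnot(is.matrix(frame))
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3")
  # the neighbourhood cannot exceed the frame; clamp to the largest odd fit
  maxw <- min(dim(frame))
  if (window > maxw) window <- maxw - (1 - maxw %% 2)
  # Gaussian kernel with the conventional size-derived sigma
  sigma <- 0.3 * ((window - 1) * 0.5 - 1) + 0.8
  k <- gaussKernel(window, sigma)
  local_mean <- EBImage::filter2(frame, k, boundary = "replicate")
  fg <- frame < (local_mean - offset)
  if (!is.null(roi)) fg <- fg & roi@mask
  fg
}

gaussKernel <- function(size, sigma) {
  ax <- seq_len(size) - (size + 1) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Covered-area time series from segmentation masks
#'
#' Converts per-frame foreground pixel counts to mm^2 with the calibrated
#' pixel pitch, and subtracts the initial (t0) area to give the
#' growth-increment series.
#'
#' @param masks list of logical matrices (one per frame).
#' @param cal a \linkS4class{ScaleCalibration}.
#' @param times_s timestamps in seconds (one per mask).
#' @param condition condition label.
#' @return an \linkS4class{AreaSeries}.
#' @export
areaSeries <- function(masks, cal, times_s, condition = "unlabelled") {
  if (length(masks) == 0L) stop("empty mask series")
  stopifnot(length(times_s) == length(masks))
  px_mm2 <- (pixelPitch(cal) / 1000)^2
  a <- vapply(masks, sum, numeric(1)) * px_mm2
  new("AreaSeries", timesH = as.numeric(times_s) / 3600,
      areaMm2 = a, areaNormMm2 = a - a[1], condition = condition)
}

# index of the timepoint nearest `hour`, required within +/- one median
# capture interval unless tolerance_h overrides
nearestTimeIndex <- function(times_h, hour, tolerance_h = NULL) {
  i <- which.min(abs(times_h - hour))
  if (is.null(tolerance_h)) {
    step <- if (length(times_h) > 1) stats::median(diff(times_h)) else Inf
    tolerance_h <- step
  }
  if (abs(times_h[i] - hour) > tolerance_h + 1e-9)
    stop(sprintf("no timepoint within tolerance of %.2f h", hour))
  i
}

#' Growth rate over the 24 h observation window
#'
#' The relative area increase `(A_t24 - A_t0) / A_t0`, computed from the raw
#' covered areas (the baseline-subtracted series is zero at t0 and is meant
#' for plotting, not for this ratio). `A_t24` is the frame nearest 24 h,
#' within one capture interval.
#'
#' @param series an \linkS4class{AreaSeries} spanning at least `horizon_h`.
#' @param horizon_h evaluation horizon in hours (default 24).
#' @return dimensionless growth rate.
#' @examples
#' s <- new("AreaSeries", timesH = c(0, 24), areaMm2 = c(50, 100),
#'          areaNormMm2 = c(0, 50), condition = "demo")
#' growthRate(s)  # 1.0
#' @export
growthRate <- function(series, horizon_h = 24) {
  if (max(series@timesH) < horizon_h - 1e-9) {
    step <- if (length(series@timesH) > 1) stats::median(diff(series@timesH)) else 0
    if (max(series@timesH) + step < horizon_h - 1e-9)
      stop(sprintf("series spans %.2f h; %g h required", max(series@timesH),
                   horizon_h))
  }
  a0 <- series@areaMm2[1]
  if (a0 <= 0) stop("initial area is zero; growth rate undefined")
  i24 <- nearestTimeIndex(series@timesH, horizon_h)
  (series@areaMm2[i24] - a0) / a0
}

#' Cumulatively-explored-area series
#'
#' Area of the running union of occupied pixels: `explored[t]` is the mm^2
#' footprint of every position reached up to time t, which separates
#' locomotion from net growth.
#'
#' @inheritParams areaSeries
#' @return an \linkS4class{ExplorationSeries}.
#' @export
explorationSeries <- function(masks, cal, times_s) {
  if (length(masks) == 0L) stop("empty mask series")
  stopifnot(length(times_s) == length(masks))
  px_mm2 <- (pixelPitch(cal) / 1000)^2
  acc <- masks[[1L]]
  explored <- numeric(length(masks))
  explored[1L] <- sum(acc) * px_mm2
  if (length(masks) > 1L) {
    for (t in 2:length(masks)) {
      acc <- acc | masks[[t]]
      explored[t] <- sum(acc) * px_mm2
    }
  }
  new("ExplorationSeries", timesH = as.numeric(times_s) / 3600,
      exploredMm2 = explored)
}

#' Exploration rate over the 24 h observation window
#'
#' `EA_t24 / 24`: explored area at 24 h divided by the 24 h horizon,
#' in mm^2 per hour.
#'
#' @param series an \linkS4class{ExplorationSeries}.
#' @param horizon_h evaluation horizon in hours (default 24).
#' @return mm^2 per hour.
#' @export
explorationRate <- function(series, horizon_h = 24) {
  if (max(series@timesH) < horizon_h - 1e-9) {
    step <- if (length(series@timesH) > 1) stats::median(diff(series@timesH)) else 0
    if (max(series@timesH) + step < horizon_h - 1e-9)
      stop(sprintf("series spans %.2f h; %g h required", max(series@timesH),
                   horizon_h))
  }
  i <- nearestTimeIndex(series@timesH, horizon_h)
  series@exploredMm2[i] / horizon_h
}

#' Growth inhibition relative to untreated controls
#'
#' The normalised difference in covered area relative to the control,
#' `(Area_c - mean(Area_c0)) / mean(Area_c0)`, per treated replicate. The
#' value is negative under inhibition; the conventional positive "growth
#' inhibition" magnitude is its negation (e.g. a treated area 25% below
#' control gives -0.25, reported as 0.25 inhibition).
#'
#' @param area_c covered areas (mm^2) of treated replicates at one
#'   concentration.
#' @param control_areas covered areas (mm^2) of untreated replicates.
#' @return signed normalised difference per treated replicate.
#' @examples
#' growthInhibition(75, c(100))        # -0.25
#' growthInhibition(80, c(90, 110))    # -0.20
#' @export
growthInhibition <- function(area_c, control_areas) {
  if (length(control_areas) < 1L) stop("at least one control replicate needed")
  m0 <- mean(control_areas)
  if (m0 <= 0) stop("control mean area must be positive")
  (area_c - m0) / m0
}

#' Fit a polynomial dose-response curve
#'
#' Least-squares polynomial fit (default degree 3) of inhibition against
#' concentration, as used for dose-response characterisation, plus the
#' per-concentration mean and standard deviation for error bars.
#'
#' @param concentrations concentration per replicate (uM).
#' @param inhibitions inhibition value per replicate.
#' @param degree polynomial degree (default 3).
#' @return list with `coefficients` (highest degree first), `fitted`,
#'   `residuals`, `summary` (per-concentration mean and sd), and the `lm`
#'   fit object.
#' @export
fitDoseResponse <- function(concentrations, inhibitions, degree = 3) {
  stopifnot(length(concentrations) == length(inhibitions))
  if (length(unique(concentrations)) < degree + 1)
    stop("need at least degree + 1 distinct concentrations")
  fit <- stats::lm(inhibitions ~ stats::poly(concentrations, degree,
                                             raw = TRUE))
  cf <- rev(unname(stats::coef(fit)))  # highest degree first
  agg <- stats::aggregate(inhibitions,
                          by = list(concentration = concentrations),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v)))
  summary_df <- data.frame(concentration = agg$concentration,
                           mean = agg$x[, "mean"], sd = agg$x[, "sd"])
  list(coefficients = cf, fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::residuals(fit)), summary = summary_df,
       fit = fit)
}
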