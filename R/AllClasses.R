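#' @import methods
#' @importFrom Rcpp sourceCpp evalCpp
#' @useDynLib myxometry, .registration = TRUE
NULL

#' Ordered, calibrated greyscale image stack
#'
#' Container for a time-lapse series: a list of 8-bit greyscale rasters
#' (numeric matrices with intensities in `[0, 255]`, row/column indexed),
#' timestamps in seconds from the first frame, and an optional spatial
#' calibration (micrometres per pixel). Two capture regimes are typical for
#' plasmodial recordings: a growth set (24 h at one frame per 60 s) and a
#' vein set (1 h at one frame per 4 s).
#'
#' @slot frames list of numeric matrices, identical dimensions, values in
#'   `[0, 255]`.
#' @slot timestamps numeric, seconds from the first frame, strictly
#'   increasing.
#' @slot pixelPitch numeric(1), micrometres per pixel (`NA_real_` until
#'   calibrated).
#' @slot sourcePaths character, provenance of each frame (may be empty).
#'
#' @seealso [loadFrameSeries()], [calibrateScale()]
#' @export
setClass("FrameSeries",
  representation(
    frames = "list",
    timestamps = "numeric",
    pixelPitch = "numeric",
    sourcePaths = "character"
  ),
  prototype(pixelPitch = NA_real_, sourcePaths = character())
)

setValidity("FrameSeries", function(object) {
  msgs <- character()
  n <- length(object@frames)
  if (n == 0L) msgs <- c(msgs, "frames must contain at least one raster")
  if (length(object@timestamps) != n)
    msgs <- c(msgs, "timestamps length must equal number of frames")
  if (n > 1L && any(diff(object@timestamps) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  if (n > 0L) {
    d <- dim(object@frames[[1L]])
    ok <- vapply(object@frames, function(f)
      is.matrix(f) && identical(dim(f), d), logical(1))
    if (!all(ok)) msgs <- c(msgs, "all frames must share identical dimensions")
    rng <- range(vapply(object@frames, function(f) range(f), numeric(2)))
    if (rng[1] < 0 || rng[2] > 255)
      msgs <- c(msgs, "frame intensities must lie in [0, 255]")
  }
  if (length(object@pixelPitch) != 1L)
    msgs <- c(msgs, "pixelPitch must be a single value")
  else if (!is.na(object@pixelPitch) &&
           (!is.finite(object@pixelPitch) || object@pixelPitch <= 0))
    msgs <- c(msgs, "pixelPitch must be finite and positive")
  if (length(msgs)) msgs else TRUE
})

#' Spatial scale calibration
#'
#' Micrometres per pixel derived from a reference object of known physical
#' size in the field of view (e.g. the 92 mm Petri-dish diameter).
#'
#' @slot pixelPitch numeric(1), micrometres per pixel, finite and positive.
#' @slot source character(1), free-text description of the reference used.
#' @seealso [calibrateScale()]
#' @export
setClass("ScaleCalibration",
  representation(pixelPitch = "numeric", source = "character"),
  prototype(source = "unspecified reference")
)

setValidity("ScaleCalibration", function(object) {
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    return("pixelPitch must be a single finite positive value")
  TRUE
})

#' Circular region-of-interest mask
#'
#' The interior of the detected Petri-dish rim: a centre, a radius, and the
#' rasterised boolean disc. Analysis is restricted to this region so the dish
#' rim and anything outside it never contribute to area counts.
#'
#' @slot center numeric(2), (row, col) of the disc centre in pixels.
#' @slot radius numeric(1), pixels.
#' @slot mask logical matrix, `TRUE` inside the disc.
#' @seealso [detectDishROI()], [applyROI()]
#' @export
setClass("ROIMask",
  representation(center = "numeric", radius = "numeric", mask = "matrix")
)

setValidity("ROIMask", function(object) {
  msgs <- character()
  if (length(object@center) != 2L) msgs <- c(msgs, "center must be (row, col)")
  if (length(object@radius) != 1L || object@radius <= 0)
    msgs <- c(msgs, "radius must be a single positive value")
  if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
  if (!length(msgs)) {
    # rasterised disc area check, only when the disc fits inside the frame
    d <- dim(object@mask)
    ctr <- object@center; r <- object@radius
    if (ctr[1] - r >= 1 && ctr[1] + r <= d[1] &&
        ctr[2] - r >= 1 && ctr[2] + r <= d[2]) {
      expect <- pi * r^2
      got <- sum(object@mask)
      if (abs(got - expect) > 0.01 * expect + 4)
        msgs <- c(msgs, sprintf(
          "mask pixel count (%d) deviates >1%% from disc area (%.0f)",
          got, expect))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Covered-area time series
#'
#' Per-timepoint area covered by the organism (mm^2), with the
#' baseline-subtracted series (area minus the area at t0) used for plotting
#' growth increments. The growth rate (A_t24 - A_t0)/A_t0 is computed from
#' the raw series.
#'
#' @slot timesH numeric, hours from the first frame.
#' @slot areaMm2 numeric, covered area per timepoint, non-negative.
#' @slot areaNormMm2 numeric, `areaMm2 - areaMm2[1]`.
#' @slot condition character(1) label (e.g. "control", "starvation").
#' @seealso [areaSeries()], [growthRate()]
#' @export
setClass("AreaSeries",
  representation(timesH = "numeric", areaMm2 = "numeric",
                 areaNormMm2 = "numeric", condition = "character"),
  prototype(condition = "unlabelled")
)

setValidity("AreaSeries", function(object) {
  msgs <- character()
  n <- length(object@timesH)
  if (n == 0L) msgs <- c(msgs, "series must be non-empty")
  if (length(object@areaMm2) != n || length(object@areaNormMm2) != n)
    msgs <- c(msgs, "timesH, areaMm2, areaNormMm2 must have equal length")
  if (n > 0L && any(object@areaMm2 < 0))
    msgs <- c(msgs, "areaMm2 must be non-negative")
  if (n > 0L && abs(object@areaNormMm2[1]) > 1e-9)
    msgs <- c(msgs, "areaNormMm2 must be zero at t0")
  if (length(msgs)) msgs else TRUE
})

#' Cumulatively-explored-area time series
#'
#' Area of the union of every pixel occupied by the organism up to each
#' timepoint (mm^2). Distinguishes locomotion from net growth: stable covered
#' area with rising explored area indicates movement.
#'
#' @slot timesH numeric, hours.
#' @slot exploredMm2 numeric, monotone non-decreasing.
#' @seealso [explorationSeries()], [explorationRate()]
#' @export
setClass("ExplorationSeries",
  representation(timesH = "numeric", exploredMm2 = "numeric")
)

setValidity("ExplorationSeries", function(object) {
  msgs <- character()
  if (length(object@timesH) != length(object@exploredMm2))
    msgs <- c(msgs, "timesH and exploredMm2 must have equal length")
  if (length(object@exploredMm2) > 1L &&
      any(diff(object@exploredMm2) < -1e-9))
    msgs <- c(msgs, "exploredMm2 must be monotone non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' Box-counting fractal dimension time series
#'
#' Fractal dimension D per subsampled timepoint, with the goodness of the
#' log-log regression and the box sizes used, so poor scaling regimes are
#' visible rather than silent.
#'
#' @slot timesH numeric, hours (typically one point per 10 min).
#' @slot dimension numeric, D in `[0, 2]` for 2D rasters.
#' @slot fitR2 numeric, R^2 of each log(count) ~ log(size) fit.
#' @slot boxSizes numeric, strictly decreasing box edge lengths (px).
#' @seealso [fractalSeries()], [fractalDimension()]
#' @export
setClass("FractalSeries",
  representation(timesH = "numeric", dimension = "numeric",
                 fitR2 = "numeric", boxSizes = "numeric")
)

setValidity("FractalSeries", function(object) {
  msgs <- character()
  if (length(object@timesH) != length(object@dimension) ||
      length(object@timesH) != length(object@fitR2))
    msgs <- c(msgs, "timesH, dimension, fitR2 must have equal length")
  if (any(object@dimension < -0.05 | object@dimension > 2.05, na.rm = TRUE))
    msgs <- c(msgs, "dimension must lie in [0, 2] for 2D rasters")
  if (length(object@boxSizes) < 2L || any(diff(object@boxSizes) >= 0))
    msgs <- c(msgs, "boxSizes must be strictly decreasing with >= 2 values")
  if (length(msgs)) msgs else TRUE
})

#' Vein measurement sections and their positions
#'
#' The set of candidate measurement sites on the vein skeleton: one row per
#' section in `sections` (detection-line endpoints, status, rejection reason)
#' and one row per measurement position in `positions` (coordinates and the
#' unit normal along which width is measured). Sections move through the
#' five-stage quality-control cascade by status update, never by deletion,
#' so the audit trail of rejections is preserved.
#'
#' @slot sections data.frame: section_id, r1, c1, r2, c2 (detection-line
#'   endpoints, pixels), n_positions, status ("active"/"rejected"),
#'   reject_reason.
#' @slot positions data.frame: section_id, pos_index, r, c, nr, nc (unit
#'   normal), keep (logical; positions dropped by the consistency check).
#' @seealso [detectSections()], [qcCascade()]
#' @export
setClass("VeinSectionSet",
  representation(sections = "data.frame", positions = "data.frame")
)

setValidity("VeinSectionSet", function(object) {
  need_s <- c("section_id", "r1", "c1", "r2", "c2", "n_positions",
              "status", "reject_reason")
  need_p <- c("section_id", "pos_index", "r", "c", "nr", "nc", "keep")
  msgs <- character()
  if (!all(need_s %in% names(object@sections)))
    msgs <- c(msgs, "sections is missing required columns")
  if (!all(need_p %in% names(object@positions)))
    msgs <- c(msgs, "positions is missing required columns")
  if (!length(msgs) && nrow(object@sections)) {
    act <- object@sections$status == "active"
    kept <- table(factor(object@positions$section_id[object@positions$keep],
                         levels = object@sections$section_id))
    if (any(kept[act] < 4L))
      msgs <- c(msgs, "active sections must retain >= 4 measurement positions")
  }
  if (length(msgs)) msgs else TRUE
})

#' Spectral estimate of the contraction frequency
#'
#' Welch power-spectral-density analysis of one vein-width trace: the
#' full-trace PSD with its interquartile-range noise threshold, per-slice
#' frequency estimates from the power-weighted seven-bin neighbourhood of the
#' spectral peak, and their average as the section's contraction frequency.
#'
#' @slot sectionId character(1).
#' @slot fs numeric(1), sampling frequency in Hz.
#' @slot n numeric(1), points per transform (Welch segment length).
#' @slot freqs numeric, one-sided frequency axis of the full-trace PSD (Hz).
#' @slot power numeric, full-trace PSD values.
#' @slot noiseThreshold numeric(1), Q3 + 1.5 IQR of the PSD.
#' @slot sliceFreqs numeric, per-slice frequency estimates (Hz).
#' @slot estFrequencyHz numeric(1), mean of the slice estimates.
#' @slot lowConfidence logical(1), `TRUE` when the spectral peak does not
#'   exceed the noise threshold.
#' @seealso [contractionFrequency()], [organismAverage()]
#' @export
setClass("SpectralEstimate",
  representation(sectionId = "character", fs = "numeric", n = "numeric",
                 freqs = "numeric", power = "numeric",
                 noiseThreshold = "numeric", sliceFreqs = "numeric",
                 estFrequencyHz = "numeric", lowConfidence = "logical"),
  prototype(sectionId = NA_character_, lowConfidence = FALSE)
)

setValidity("SpectralEstimate", function(object) {
  msgs <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive value")
  if (length(object@estFrequencyHz) == 1L && !is.na(object@estFrequencyHz) &&
      length(object@fs) == 1L &&
      (object@estFrequencyHz <= 0 || object@estFrequencyHz >= object@fs / 2))
    msgs <- c(msgs, "estFrequencyHz must lie in (0, fs/2)")
  if (length(object@noiseThreshold) == 1L && !is.na(object@noiseThreshold) &&
      object@noiseThreshold < 0)
    msgs <- c(msgs, "noiseThreshold must be non-negative")
  if (length(object@sliceFreqs) < 1L)
    msgs <- c(msgs, "at least one Welch slice is required")
  if (length(msgs)) msgs else TRUE
})

#' Binned vein-diameter distribution
#'
#' Vein diameters pooled over the network and divided into equal-width
#' intervals between the minimum and maximum observed diameter; the
#' proportion of measurements in each interval drives the per-interval
#' length and volume computation.
#'
#' @slot edges numeric, interval boundaries (micrometres), length
#'   `nIntervals + 1`.
#' @slot centers numeric, interval mid-diameters 2r (micrometres), strictly
#'   increasing.
#' @slot p numeric, proportion of measurements per interval, sums to 1.
#' @slot stepsize numeric(1), interval width = (max - min)/nIntervals (um).
#' @slot delta numeric(1), max - min diameter (um).
#' @slot nIntervals numeric(1).
#' @seealso [diameterDistribution()], [estimateVolume()]
#' @export
setClass("DiameterDistribution",
  representation(edges = "numeric", centers = "numeric", p = "numeric",
                 stepsize = "numeric", delta = "numeric",
                 nIntervals = "numeric")
)

setValidity("DiameterDistribution", function(object) {
  msgs <- character()
  n <- object@nIntervals
  if (length(object@p) != n || length(object@centers) != n ||
      length(object@edges) != n + 1)
    msgs <- c(msgs, "edges/centers/p lengths inconsistent with nIntervals")
  if (abs(sum(object@p) - 1) > 1e-9)
    msgs <- c(msgs, "proportions must sum to 1")
  if (n > 1 && any(diff(object@centers) <= 0))
    msgs <- c(msgs, "centers must be strictly increasing")
  if (n >= 1 && abs(object@stepsize - object@delta / n) > 1e-9 * max(1, object@delta))
    msgs <- c(msgs, "stepsize must equal delta / nIntervals")
  if (length(msgs)) msgs else TRUE
})

#' Estimated network volume with geometric error bounds
#'
#' Total network volume from summing per-diameter-interval cylinder volumes,
#' the volume normalised by the 2D biomass area at 24 h (an effective mean
#' network thickness, mm), and the relative-error bounds for circular-segment
#' and elliptical vein cross-sections.
#'
#' @slot totalMm3 numeric(1).
#' @slot perInterval data.frame: r_mm (interval radius), l_mm (estimated
#'   length), volume_mm3.
#' @slot normalizedMm numeric(1), totalMm3 / areaMm2.
#' @slot areaMm2 numeric(1), the 24 h network area used.
#' @slot errorRange list with elements eps_segment, eps_ellipse, alpha_max,
#'   x_max and volume_interval (the implied `[total/(1+eps_max), total]`).
#' @seealso [estimateVolume()], [segmentError()], [ellipseError()]
#' @export
setClass("VolumeEstimate",
  representation(totalMm3 = "numeric", perInterval = "data.frame",
                 normalizedMm = "numeric", areaMm2 = "numeric",
                 errorRange = "list"),
  prototype(errorRange = list())
)

setValidity("VolumeEstimate", function(object) {
  msgs <- character()
  if (object@totalMm3 < 0 || object@normalizedMm < 0)
    msgs <- c(msgs, "volume components must be non-negative")
  if (nrow(object@perInterval) &&
      abs(sum(object@perInterval$volume_mm3) - object@totalMm3) >
        1e-9 * max(1, object@totalMm3))
    msgs <- c(msgs, "total must equal the sum of per-interval volumes")
  if (length(msgs)) msgs else TRUE
})
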