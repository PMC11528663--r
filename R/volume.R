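#' Bin vein diameters into equal-width intervals
#'
#' Divides the pooled diameter sample into `n_intervals` equal-width
#' intervals between the minimum and maximum diameter
#' (`stepsize = (max - min)/n`), half-open with the last interval closed,
#' and records the proportion of measurements falling into each. Fifty
#' intervals are the standard resolution for network-volume estimation.
#'
#' @param widths vein diameters in micrometres (positive).
#' @param n_intervals number of intervals (default 50).
#' @return a \linkS4class{DiameterDistribution}. When all widths are equal
#'   the distribution degenerates to a single interval (with a warning).
#' @export
diameterDistribution <- function(widths, n_intervals = 50) {
  widths <- widths[is.finite(widths)]
  if (!length(widths) || all(widths <= 0))
    stop("at least one positive width is required")
  widths <- widths[widths > 0]
  lo <- min(widths); hi <- max(widths)
  if (hi <= lo) {
    warning("all widths equal: degenerate single-interval distribution")
    return(new("DiameterDistribution", edges = c(lo, lo), centers = lo,
               p = 1, stepsize = 0, delta = 0, nIntervals = 1))
  }
  step <- (hi - lo) / n_intervals
  edges <- lo + step * (0:n_intervals)
  k <- pmin(floor((widths - lo) / step) + 1L, n_intervals)  # last closed
  p <- tabulate(k, nbins = n_intervals) / length(widths)
  new("DiameterDistribution", edges = edges,
      centers = (edges[-1] + edges[-(n_intervals + 1)]) / 2,
      p = p, stepsize = step, delta = hi - lo, nIntervals = n_intervals)
}

#' Network length represented by one diameter interval
#'
#' `l = area * p / (2r)`: the projected area attributed to the interval
#' (total network area times the interval's proportion) divided by the
#' interval's diameter, giving the length of network with that diameter.
#' For a single uniform cylinder (projected area `2 r L`, p = 1) this
#' recovers L exactly.
#'
#' @param area_mm2 total 2D network area at 24 h (mm^2).
#' @param p proportion of diameter measurements in the interval.
#' @param two_r_mm interval diameter 2r in millimetres.
#' @return length in millimetres.
#' @export
intervalLength <- function(area_mm2, p, two_r_mm) {
  if (any(two_r_mm <= 0)) stop("interval diameter must be positive")
  area_mm2 * p / two_r_mm
}

#' Estimate total network volume from the diameter distribution
#'
#' Treats the network as a collection of cylindrical sections, one per
#' diameter interval: each interval's length comes from
#' [intervalLength()] and its volume is `pi r^2 l` with r half the interval
#' centre; the total is the sum over intervals. The normalised volume
#' (total / area) is an effective mean network thickness in mm.
#'
#' @param dist a \linkS4class{DiameterDistribution} (centres in um).
#' @param area_mm2 2D network area at 24 h (mm^2).
#' @param alpha_max worst-case circular-segment angle for the error range
#'   (radians; default `pi/2`).
#' @param x_max worst-case elliptical flattening as a fraction of r
#'   (default 0.5).
#' @return a \linkS4class{VolumeEstimate}.
#' @export
estimateVolume <- function(dist, area_mm2, alpha_max = pi / 2,
                           x_max = 0.5) {
  if (area_mm2 < 0) stop("area must be non-negative")
  two_r_mm <- dist@centers / 1000
  r_mm <- two_r_mm / 2
  l_mm <- ifelse(dist@p > 0, intervalLength(area_mm2, dist@p, two_r_mm), 0)
  vol <- pi * r_mm^2 * l_mm
  total <- sum(vol)
  eps_s <- segmentError(alpha_max)
  eps_e <- ellipseError(x_max * 1, 1)      # scale-free in x/r
  eps_max <- max(eps_s, eps_e)
  new("VolumeEstimate",
      totalMm3 = total,
      perInterval = data.frame(r_mm = r_mm, l_mm = l_mm, volume_mm3 = vol),
      normalizedMm = if (area_mm2 > 0) total / area_mm2 else 0,
      areaMm2 = area_mm2,
      errorRange = list(eps_segment = eps_s, eps_ellipse = eps_e,
                        alpha_max = alpha_max, x_max = x_max,
                        volume_interval = c(total / (1 + eps_max), total)))
}

#' Normalised network volume
#'
#' Total estimated volume divided by the 2D biomass area at 24 h; with units
#' mm^3 / mm^2 = mm this is an effective mean thickness of the network.
#'
#' @param vol a \linkS4class{VolumeEstimate} (or total volume in mm^3).
#' @param area_mm2_at_24h the 24 h covered area (mm^2, positive).
#' @return normalised volume in mm.
#' @export
normalizedVolume <- function(vol, area_mm2_at_24h) {
  total <- if (is(vol, "VolumeEstimate")) vol@totalMm3 else as.numeric(vol)
  if (area_mm2_at_24h <= 0) stop("area must be positive")
  total / area_mm2_at_24h
}

#' Relative volume error for a circular-segment cross-section
#'
#' If a vein's true cross-section is a circle truncated by a chord
#' subtending angle `alpha` (a vein flattened against the substrate), the
#' circular assumption overestimates the cross-section area; the relative
#' error is `(alpha - sin(alpha)) / (2*pi - (alpha - sin(alpha)))`, 0 for a
#' full circle and 1 when half the disc is missing.
#'
#' @param alpha subtended angle in radians, `0 <= alpha < 2*pi`.
#' @return relative error epsilon_S.
#' @examples
#' segmentError(0)   # 0
#' segmentError(pi)  # 1
#' @export
segmentError <- function(alpha) {
  if (any(alpha < 0 | alpha >= 2 * pi))
    stop("alpha must lie in [0, 2*pi)")
  (alpha - sin(alpha)) / (2 * pi - (alpha - sin(alpha)))
}

#' Relative volume error for an elliptical cross-section
#'
#' If the true cross-section is an ellipse with the same horizontal diameter
#' 2r but vertical diameter reduced by `x`, the relative error of the
#' circular assumption is `x / (2r - x)`: 0 in the circular case and 1 when
#' the minor axis is halved.
#'
#' @param x flattening (same length unit as r), `0 <= x < 2r`.
#' @param r radius.
#' @return relative error epsilon_E.
#' @examples
#' ellipseError(0, 1)  # 0
#' ellipseError(1, 1)  # 1
#' @export
ellipseError <- function(x, r) {
  if (any(x < 0 | x >= 2 * r))
    stop("x must lie in [0, 2r)")
  x / (2 * r - x)
}

#' Tabulated error curves over parameter grids
#'
#' Evaluates the circular-segment and elliptical relative-error formulas
#' over grids of their shape parameters, for plotting the worst-case
#' envelope of the volume estimate.
#'
#' @param alpha_grid circular-segment angles (radians).
#' @param x_grid elliptical flattenings (same unit as `r`).
#' @param r radius for the elliptical error.
#' @return list of two data frames: `segment` (alpha, eps_s) and `ellipse`
#'   (x, eps_e); empty grids give empty tables.
#' @export
errorCurves <- function(alpha_grid, x_grid, r = 1) {
  list(
    segment = data.frame(alpha = alpha_grid,
                         eps_s = if (length(alpha_grid))
                           segmentError(alpha_grid) else numeric()),
    ellipse = data.frame(x = x_grid,
                         eps_e = if (length(x_grid))
                           ellipseError(x_grid, r) else numeric())
  )
}
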