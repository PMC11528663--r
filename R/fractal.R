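#' Count occupied boxes at one grid scale
#'
#' Number of `box_size` x `box_size` grid cells containing at least one
#' foreground pixel. The grid is anchored at the mask's bounding-box corner
#' (falling back to the raster origin for an empty mask), which makes the
#' count invariant to translation and background padding.
#'
#' @param mask logical matrix.
#' @param box_size box edge length in pixels, >= 1.
#' @param anchor "bbox" (default) or "origin" grid anchoring.
#' @return integer count of occupied boxes (0 for an empty mask).
#' @export
boxCount <- function(mask, box_size, anchor = c("bbox", "origin")) {
  stopifnot(is.matrix(mask), box_size >= 1)
  anchor <- match.arg(anchor)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  if (anchor == "bbox") {
    r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  } else {
    r0 <- 1L; c0 <- 1L
  }
  br <- (idx[, 1] - r0) %/% box_size
  bc <- (idx[, 2] - c0) %/% box_size
  length(unique(br * (max(bc) + 1L) + bc))
}

#' Box-counting fractal dimension of a binary raster
#'
#' D is the negative slope of the least-squares fit of `log(count)` against
#' `log(box_size)` over a range of grid scales: ~1 for line-like patterns,
#' ~2 for space-filling ones. Box sizes default to descending powers of two
#' between `min(dim)/4` and 2 px; the R^2 of the fit is returned so poor
#' scaling regimes are visible.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param box_sizes optional vector of box sizes (pixels), >= 3 values.
#' @return list with `dimension`, `fit_r2`, `box_sizes`, `counts`.
#' @examples
#' sq <- matrix(TRUE, 64, 64)
#' fractalDimension(sq)$dimension  # ~2
#' @export
fractalDimension <- function(mask, box_sizes = NULL) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("empty mask: fractal dimension undefined")
  if (is.null(box_sizes)) box_sizes <- defaultBoxSizes(dim(mask))
  box_sizes <- sort(unique(as.integer(box_sizes)), decreasing = TRUE)
  if (length(box_sizes) < 3L)
    stop("at least 3 box sizes are required (raster too small?)")
  counts <- vapply(box_sizes, function(s) as.numeric(boxCount(mask, s)),
                   numeric(1))
  fit <- stats::lm(log(counts) ~ log(box_sizes))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(counts) - mean(log(counts)))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(dimension = -unname(stats::coef(fit)[2]), fit_r2 = r2,
       box_sizes = box_sizes, counts = counts)
}

defaultBoxSizes <- function(d) {
  smax <- floor(min(d) / 4)
  if (smax < 2) stop("raster too small for box counting")
  2^(seq.int(1, floor(log2(smax))))
}

#' Fractal-dimension time series on a temporally subsampled mask series
#'
#' Computes D on the segmentation mask temporally nearest each point of a
#' regular grid (default one point per 10 min), the standard thinning of a
#' one-frame-per-minute growth recording.
#'
#' @param masks list of logical matrices.
#' @param times_s timestamps in seconds, one per mask.
#' @param every_minutes subsampling interval (default 10).
#' @param box_sizes optional box sizes passed to [fractalDimension()].
#' @return a \linkS4class{FractalSeries}.
#' @export
fractalSeries <- function(masks, times_s, every_minutes = 10,
                          box_sizes = NULL) {
  stopifnot(length(masks) == length(times_s), length(masks) >= 1L)
  grid_s <- seq(min(times_s), max(times_s), by = every_minutes * 60)
  if (length(grid_s) == 0L) stop("empty temporal subsample")
  picks <- vapply(grid_s, function(g) which.min(abs(times_s - g)), integer(1))
  res <- lapply(picks, function(i) fractalDimension(masks[[i]], box_sizes))
  new("FractalSeries",
      timesH = grid_s / 3600,
      dimension = vapply(res, `[[`, numeric(1), "dimension"),
      fitR2 = vapply(res, `[[`, numeric(1), "fit_r2"),
      boxSizes = as.numeric(res[[1L]]$box_sizes))
}
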