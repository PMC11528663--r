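# Seeded synthetic image generator. Every phantom is reproducible
# bit-for-bit from its parameters + seed and is emitted together with the
# ground truth needed to oracle the analysis stages.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

addNoise <- function(frame, sd) {
  if (sd <= 0) return(frame)
  pmin(pmax(frame + stats::rnorm(length(frame), 0, sd), 0), 255)
}

pixelGrid <- function(d) {
  list(r = matrix(seq_len(d[1]), d[1], d[2]),
       c = matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE))
}

# coverage of an anti-aliased disc edge: 1 inside, 0 outside, linear ramp
discCoverage <- function(g, center, radius, antialias = TRUE) {
  dist <- sqrt((g$r - center[1])^2 + (g$c - center[2])^2)
  if (antialias) pmin(pmax(radius + 0.5 - dist, 0), 1)
  else (dist <= radius) + 0
}

strokeCoverage <- function(g, p1, p2, width_px, antialias = TRUE) {
  v <- c(p2[1] - p1[1], p2[2] - p1[2])
  L2 <- sum(v^2)
  wr <- g$r - p1[1]; wc <- g$c - p1[2]
  t <- if (L2 > 0) pmin(pmax((wr * v[1] + wc * v[2]) / L2, 0), 1) else 0
  dist <- sqrt((wr - t * v[1])^2 + (wc - t * v[2])^2)
  if (antialias) pmin(pmax(width_px / 2 + 0.5 - dist, 0), 1)
  else (dist <= width_px / 2) + 0
}

compositeStrokes <- function(d, segs, fg = 60, bg = 200, antialias = TRUE) {
  g <- pixelGrid(d)
  cov <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(segs)))
    cov <- pmax(cov, strokeCoverage(g, c(segs$r1[i], segs$c1[i]),
                                    c(segs$r2[i], segs$c2[i]),
                                    segs$width_px[i], antialias))
  bg + (fg - bg) * cov
}

#' Phantom Petri dish
#'
#' A bright agar interior inside a dark dish rim on a dimmer exterior, the
#' oracle input for circular-ROI detection. `radius` is the rim's inner
#' edge, i.e. the boundary of the usable growth region that ROI detection
#' should recover; the dark rim ring extends `rim_width` px beyond it.
#'
#' @param dim frame dimensions `c(rows, cols)`.
#' @param center rim centre (row, col); defaults to the frame centre.
#' @param radius inner rim radius in pixels (must fit inside the frame).
#' @param rim_width rim ring thickness (px).
#' @param interior,rim,exterior intensities.
#' @param noise_sd additive Gaussian noise sd (clipped to `[0, 255]`).
#' @param seed RNG seed for the noise.
#' @return list with `frame` (matrix) and `truth` (centre, radius).
#' @export
makeDish <- function(dim = c(240, 240), center = (dim + 1) / 2,
                     radius = 90, rim_width = 6, interior = 200, rim = 40,
                     exterior = 120, noise_sd = 0, seed = NULL) {
  if (radius + rim_width >= min(center, dim - center + 1))
    stop("dish rim does not fit inside the frame")
  g <- pixelGrid(dim)
  dist <- sqrt((g$r - center[1])^2 + (g$c - center[2])^2)
  frame <- matrix(exterior, dim[1], dim[2])
  frame[dist < radius + rim_width] <- rim
  frame[dist <= radius] <- interior
  frame <- withSeed(seed, addNoise(frame, noise_sd))
  list(frame = frame, truth = list(center = center, radius = radius))
}

#' Phantom growing- or translating-disc series
#'
#' A dark disc on a bright field. In "grow" mode the radius increases
#' linearly, `r(t) = r0 + k t`; `double_at_h` instead solves k so the disc
#' area exactly doubles at that horizon (the canonical growth-rate-1
#' fixture). In "translate" mode a constant-radius disc moves by a fixed
#' displacement per frame, the exploration-union fixture.
#'
#' @param dim frame dimensions.
#' @param r0 initial radius (px).
#' @param k radius growth rate (px per hour) in "grow" mode.
#' @param double_at_h if set, overrides `k` so the area doubles here.
#' @param mode "grow" or "translate".
#' @param step_px per-frame displacement `c(dr, dc)` in "translate" mode.
#' @param center0 initial disc centre (row, col); defaults to the frame
#'   centre.
#' @param n_frames,interval_s series length and capture interval.
#' @param fg,bg disc and field intensities.
#' @param pixel_pitch micrometres per pixel recorded on the series.
#' @param antialias smooth disc edges (default TRUE); hard edges make the
#'   rasterised pixel count exact for counting oracles.
#' @param noise_sd,seed noise model.
#' @return list with `series` (\linkS4class{FrameSeries}) and `truth`
#'   (per-frame radius/centre, analytic disc area in mm^2, and the
#'   rasterised pixel count `area_px`).
#' @export
makeGrowingDiskSeries <- function(dim = c(200, 200), r0 = 30, k = 1,
                                  double_at_h = NULL,
                                  mode = c("grow", "translate"),
                                  step_px = c(0, 2 * r0), center0 = NULL,
                                  n_frames = 25, interval_s = 3600,
                                  fg = 60, bg = 200, pixel_pitch = 100,
                                  antialias = TRUE, noise_sd = 0,
                                  seed = NULL) {
  mode <- match.arg(mode)
  t_h <- (seq_len(n_frames) - 1) * interval_s / 3600
  ctr0 <- if (is.null(center0)) (dim + 1) / 2 else center0
  if (mode == "grow") {
    if (!is.null(double_at_h)) {
      k <- r0 * (sqrt(2) - 1) / double_at_h
      if (!antialias) {
        # in exact-count mode, pick the end radius whose rasterised pixel
        # count doubles the initial count, so the doubling is exact on the
        # raster and not subject to O(r) boundary jitter
        g0 <- pixelGrid(dim)
        cnt <- function(r) sum((g0$r - ctr0[1])^2 + (g0$c - ctr0[2])^2 <= r^2)
        target <- 2L * cnt(r0)
        cand <- seq(r0 * sqrt(2) - 1, r0 * sqrt(2) + 1, by = 0.01)
        r_end <- cand[which.min(abs(vapply(cand, cnt, numeric(1)) - target))]
        k <- (r_end - r0) / double_at_h
      }
    }
    radii <- r0 + k * t_h
    centers <- matrix(rep(ctr0, each = n_frames), ncol = 2)
  } else {
    radii <- rep(r0, n_frames)
    centers <- cbind(ctr0[1] + (seq_len(n_frames) - 1) * step_px[1],
                     ctr0[2] + (seq_len(n_frames) - 1) * step_px[2])
  }
  if (any(radii >= min(dim) / 2) ||
      any(centers[, 1] - radii < 1) || any(centers[, 1] + radii > dim[1]) ||
      any(centers[, 2] - radii < 1) || any(centers[, 2] + radii > dim[2]))
    stop("disc leaves the frame; enlarge dim or reduce k/step/n_frames")
  g <- pixelGrid(dim)
  area_px <- integer(n_frames)
  frm <- withSeed(seed, lapply(seq_len(n_frames), function(i) {
    cov <- discCoverage(g, centers[i, ], radii[i], antialias)
    area_px[i] <<- sum(cov >= 0.5)
    addNoise(bg + (fg - bg) * cov, noise_sd)
  }))
  series <- frameSeries(frm, timestamps = (seq_len(n_frames) - 1) * interval_s,
                        pixelPitch = pixel_pitch)
  truth <- data.frame(t_h = t_h, radius_px = radii,
                      center_r = centers[, 1], center_c = centers[, 2],
                      area_mm2 = pi * radii^2 * (pixel_pitch / 1000)^2,
                      area_px = area_px)
  list(series = series, truth = truth)
}

#' Phantom vein network
#'
#' Dark anti-aliased strokes of specified widths on a bright field, with the
#' per-stroke geometry emitted as ground truth: the oracle for
#' skeletonization, section detection, width recovery and the
#' cylinder-volume identity.
#'
#' @param dim frame dimensions.
#' @param widths_px stroke widths in pixels (recycled over strokes).
#' @param n_strokes number of strokes.
#' @param layout "parallel" (disjoint horizontal strokes), "star" (strokes
#'   radiating from the centre) or "random" (random chords).
#' @param margin frame-border clearance in pixels.
#' @param fg,bg stroke and field intensities.
#' @param antialias smooth stroke edges (default TRUE); hard edges give
#'   exact pixel counts.
#' @param noise_sd,seed noise model.
#' @return list with `frame`, `truth` (per-stroke endpoints, width, length),
#'   `total_length_px`, `projected_area_px2`.
#' @export
makeVeinNetwork <- function(dim = c(200, 260), widths_px = 9, n_strokes = 4,
                            layout = c("parallel", "star", "random"),
                            margin = 20, fg = 60, bg = 200,
                            antialias = TRUE, noise_sd = 0, seed = NULL) {
  layout <- match.arg(layout)
  widths_px <- rep_len(widths_px, n_strokes)
  withSeed(seed, {
    if (layout == "parallel") {
      rows <- seq(margin, dim[1] - margin, length.out = n_strokes)
      segs <- data.frame(r1 = rows, c1 = margin, r2 = rows,
                         c2 = dim[2] - margin, width_px = widths_px)
    } else if (layout == "star") {
      ctr <- (dim + 1) / 2
      ang <- seq(0, 2 * pi, length.out = n_strokes + 1)[-(n_strokes + 1)]
      rad <- min(dim) / 2 - margin
      segs <- data.frame(r1 = ctr[1], c1 = ctr[2],
                         r2 = ctr[1] + rad * sin(ang),
                         c2 = ctr[2] + rad * cos(ang),
                         width_px = widths_px)
    } else {
      segs <- data.frame(
        r1 = stats::runif(n_strokes, margin, dim[1] - margin),
        c1 = stats::runif(n_strokes, margin, dim[2] - margin),
        r2 = stats::runif(n_strokes, margin, dim[1] - margin),
        c2 = stats::runif(n_strokes, margin, dim[2] - margin),
        width_px = widths_px)
    }
    segs$length_px <- sqrt((segs$r2 - segs$r1)^2 + (segs$c2 - segs$c1)^2)
    frame <- addNoise(compositeStrokes(dim, segs, fg, bg, antialias),
                      noise_sd)
    list(frame = frame, truth = segs,
         total_length_px = sum(segs$length_px),
         projected_area_px2 = sum(segs$length_px * segs$width_px))
  })
}

#' Phantom pulsating-vein series
#'
#' Horizontal veins whose widths oscillate as
#' `w(t) = w0 * (1 + a * sin(2*pi*f*t + phi))`, sampled at `fs` for
#' `n_frames` frames (defaults: 900 frames at 0.25 Hz, the 1 h vein
#' regime). The oracle fixture for width tracking and contraction-frequency
#' recovery. `freq_hz` may be a two-element range for a linear chirp.
#'
#' @param dim frame dimensions.
#' @param n_veins number of parallel veins.
#' @param width0_px baseline stroke width(s), recycled.
#' @param amplitude fractional modulation amplitude a.
#' @param freq_hz modulation frequency (Hz), or `c(f0, f1)` for a chirp.
#' @param phase phase offset(s), recycled; `NULL` draws random phases.
#' @param n_frames,fs series length and sampling frequency.
#' @param fg,bg stroke and field intensities.
#' @param noise_sd,seed noise model.
#' @return list with `series` (\linkS4class{FrameSeries}), `truth`
#'   (data frame `vein, t_seconds, width_px`) and `veins` (per-vein row,
#'   width0, phase).
#' @export
makePulsatingSeries <- function(dim = c(120, 160), n_veins = 1,
                                width0_px = 10, amplitude = 0.2,
                                freq_hz = 0.010, phase = 0, n_frames = 900,
                                fs = 0.25, fg = 60, bg = 200,
                                noise_sd = 0, seed = NULL) {
  if (max(freq_hz) >= fs / 2)
    stop("modulation frequency must be below the Nyquist limit fs/2")
  width0_px <- rep_len(width0_px, n_veins)
  withSeed(seed, {
    phase <- if (is.null(phase)) stats::runif(n_veins, 0, 2 * pi)
             else rep_len(phase, n_veins)
    rows <- seq(dim[1] / (n_veins + 1), dim[1] * n_veins / (n_veins + 1),
                length.out = n_veins)
    t_s <- (seq_len(n_frames) - 1) / fs
    finst <- if (length(freq_hz) == 2L)
      freq_hz[1] + (freq_hz[2] - freq_hz[1]) * t_s / max(t_s) else freq_hz[1]
    # phase of a linear chirp integrates the instantaneous frequency
    ph_t <- if (length(freq_hz) == 2L)
      2 * pi * (freq_hz[1] * t_s +
                (freq_hz[2] - freq_hz[1]) * t_s^2 / (2 * max(t_s)))
    else 2 * pi * freq_hz[1] * t_s
    g <- pixelGrid(dim)
    truth <- vector("list", n_frames)
    frm <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      w <- width0_px * (1 + amplitude * sin(ph_t[i] + phase))
      segs <- data.frame(r1 = rows, c1 = 5, r2 = rows, c2 = dim[2] - 4,
                         width_px = w)
      frm[[i]] <- addNoise(compositeStrokes(dim, segs, fg, bg), noise_sd)
      truth[[i]] <- data.frame(vein = seq_len(n_veins), t_seconds = t_s[i],
                               width_px = w)
    }
    list(series = frameSeries(frm, timestamps = t_s, pixelPitch = NA_real_),
         truth = do.call(rbind, truth),
         veins = data.frame(vein = seq_len(n_veins), row = rows,
                            width0_px = width0_px, phase = phase))
  })
}

#' Phantom patterns of known fractal dimension
#'
#' Exact rasterisations with analytic box-counting dimension: a straight
#' line (D = 1), a filled square (D = 2), and the Sierpinski triangle
#' (D = log 3 / log 2 ~ 1.585), the standard calibration targets for a
#' box-counting estimator.
#'
#' @param kind "line", "filled_square" or "sierpinski".
#' @param depth recursion depth for the Sierpinski pattern (raster is
#'   `2^depth` square).
#' @param size raster size for line / filled square.
#' @return list with `mask` (logical matrix) and `dimension` (analytic D).
#' @export
makeFractalPattern <- function(kind = c("line", "filled_square",
                                        "sierpinski"),
                               depth = 7, size = 128) {
  kind <- match.arg(kind)
  if (kind == "line") {
    m <- matrix(FALSE, size, size)
    m[floor(size / 2), ] <- TRUE
    return(list(mask = m, dimension = 1))
  }
  if (kind == "filled_square")
    return(list(mask = matrix(TRUE, size, size), dimension = 2))
  n <- 2^depth
  i <- matrix(0:(n - 1), n, n)
  j <- matrix(0:(n - 1), n, n, byrow = TRUE)
  list(mask = matrix(bitwAnd(i, j) == 0L, n, n),
       dimension = log(3) / log(2))
}

#' Write a FrameSeries (or single frame) to PNG files
#'
#' @param x a \linkS4class{FrameSeries} or a numeric matrix in `[0, 255]`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeFrames <- function(x, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frm <- if (is(x, "FrameSeries")) frames(x) else list(x)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_along(frm)))
  for (i in seq_along(frm))
    png::writePNG(frm[[i]] / 255, paths[i])
  invisible(paths)
}
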