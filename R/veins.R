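#' Skeletonize a binary vein mask
#'
#' Iterative morphological thinning (Zhang-Suen) down to a one-pixel-wide,
#' 8-connected skeleton along the centre of each vein, preserving topology.
#'
#' @param mask logical matrix (vein segmentation).
#' @return logical matrix skeleton; empty mask gives an empty skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(mask & FALSE)
  thin_cpp(mask)
}

# bilinear intensity sampling, vectorized over (r, c)
bilinearSample <- function(frame, r, c) {
  nr <- nrow(frame); nc <- ncol(frame)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  frame[i00] * (1 - fr) * (1 - fc) + frame[i10] * fr * (1 - fc) +
    frame[i01] * (1 - fr) * fc + frame[i11] * fr * fc
}

#' Detect straight measurement sections on a skeleton
#'
#' Finds straight line segments on the one-pixel skeleton with a Hough
#' transform (accumulator peaks above `threshold`, collinear runs at least
#' `min_line_length` px long with gaps below `max_gap`), then populates each
#' segment with at least four equally spaced measurement positions and the
#' unit normal along which width will be measured.
#'
#' @param skeleton logical matrix from [skeletonize()].
#' @param rho_res accumulator distance resolution (px, default 1).
#' @param theta_res accumulator angle resolution (radians, default pi/180).
#' @param threshold minimum accumulator votes for a candidate line.
#' @param min_line_length minimum segment length in pixels.
#' @param max_gap largest tolerated gap between collinear skeleton pixels.
#' @param spacing measurement-position spacing along the segment (px).
#' @param min_positions minimum measurement positions per section.
#' @return a \linkS4class{VeinSectionSet} (all sections "active").
#' @export
detectSections <- function(skeleton, rho_res = 1, theta_res = pi / 180,
                           threshold = 25, min_line_length = 10,
                           max_gap = 3, spacing = 5, min_positions = 4) {
  stopifnot(is.matrix(skeleton))
  pts <- which(skeleton, arr.ind = TRUE)
  emptySet <- function() {
    if (nrow(pts) == 0L) warning("empty skeleton: no sections detected")
    else warning("no line sections found on skeleton")
    new("VeinSectionSet", sections = emptySectionsDF(),
        positions = emptyPositionsDF())
  }
  if (nrow(pts) == 0L) return(emptySet())
  y <- pts[, 1]; x <- pts[, 2]          # rows, cols
  thetas <- seq(0, pi - theta_res / 2, by = theta_res)
  D <- ceiling(sqrt(nrow(skeleton)^2 + ncol(skeleton)^2))
  nrho <- 2L * ceiling(D / rho_res) + 1L
  rho0 <- -ceiling(D / rho_res)
  nth <- length(thetas)
  cs <- cos(thetas); sn <- sin(thetas)
  used <- rep(FALSE, length(x))
  blocked <- matrix(FALSE, nrho, nth)
  segs <- list()
  repeat {
    alive <- which(!used)
    if (length(alive) < threshold) break
    rho <- outer(x[alive], cs) + outer(y[alive], sn)
    ridx <- round(rho / rho_res) - rho0 + 1L
    lin <- (rep(seq_len(nth), each = length(alive)) - 1L) * nrho +
      as.integer(ridx)
    acc <- tabulate(lin, nbins = nrho * nth)
    acc[which(blocked)] <- 0L
    best <- which.max(acc)
    if (acc[best] < threshold) break
    bt <- (best - 1L) %/% nrho + 1L
    br <- best - (bt - 1L) * nrho
    rho_star <- (br - 1L + rho0) * rho_res
    d <- abs(x[alive] * cs[bt] + y[alive] * sn[bt] - rho_star)
    sel <- alive[d <= max(1, rho_res)]
    # order along the line direction and split at gaps
    tproj <- -x[sel] * sn[bt] + y[sel] * cs[bt]
    o <- order(tproj)
    sel <- sel[o]; tproj <- tproj[o]
    breaks <- c(0L, which(diff(tproj) > max_gap), length(sel))
    found <- FALSE
    for (k in seq_len(length(breaks) - 1L)) {
      run <- sel[(breaks[k] + 1L):breaks[k + 1L]]
      if (length(run) < 2L) next
      # span + 1 equals the pixel count of a contiguous run
      len <- tproj[breaks[k + 1L]] - tproj[breaks[k] + 1L] + 1
      if (len >= min_line_length) {
        a <- run[1L]; b <- run[length(run)]
        segs[[length(segs) + 1L]] <-
          c(y[a], x[a], y[b], x[b])
        used[run] <- TRUE
        found <- TRUE
      }
    }
    if (!found) blocked[br, bt] <- TRUE
  }
  if (!length(segs)) return(emptySet())
  buildSectionSet(segs, spacing = spacing, min_positions = min_positions)
}

emptySectionsDF <- function() {
  data.frame(section_id = integer(), r1 = numeric(), c1 = numeric(),
             r2 = numeric(), c2 = numeric(), n_positions = integer(),
             status = character(), reject_reason = character(),
             stringsAsFactors = FALSE)
}

emptyPositionsDF <- function() {
  data.frame(section_id = integer(), pos_index = integer(), r = numeric(),
             c = numeric(), nr = numeric(), nc = numeric(), keep = logical(),
             stringsAsFactors = FALSE)
}

buildSectionSet <- function(segs, spacing = 5, min_positions = 4) {
  sec <- list(); pos <- list()
  for (id in seq_along(segs)) {
    s <- segs[[id]]
    dr <- s[3] - s[1]; dc <- s[4] - s[2]
    len <- sqrt(dr^2 + dc^2)
    u <- c(dr, dc) / len
    n <- c(-u[2], u[1])                       # unit normal
    npos <- max(min_positions, floor(len / spacing) + 1L)
    tt <- seq(0, len, length.out = npos)
    sec[[id]] <- data.frame(section_id = id, r1 = s[1], c1 = s[2],
                            r2 = s[3], c2 = s[4], n_positions = npos,
                            status = "active", reject_reason = "",
                            stringsAsFactors = FALSE)
    pos[[id]] <- data.frame(section_id = id, pos_index = seq_len(npos),
                            r = s[1] + tt * u[1], c = s[2] + tt * u[2],
                            nr = n[1], nc = n[2], keep = TRUE,
                            stringsAsFactors = FALSE)
  }
  new("VeinSectionSet", sections = do.call(rbind, sec),
      positions = do.call(rbind, pos))
}

#' Measure vein width along a normal ray
#'
#' Marches from a position on the vein outwards along both directions of the
#' unit normal, in sub-pixel steps with bilinear intensity sampling, until
#' the background intensity criterion is met on each side; the width is the
#' sum of the two ray lengths scaled by the pixel pitch. Veins are dark on a
#' bright background, so the default stop rule halts at the first sample
#' brighter than the midpoint between the intensity at the position and the
#' background level (frame median unless given).
#'
#' @param frame denoised greyscale matrix.
#' @param position numeric(2) (row, col) on the vein.
#' @param normal numeric(2) unit normal of the detection line.
#' @param pixel_pitch micrometres per pixel (default 1: width in px units).
#' @param threshold stop intensity; `NULL` derives the midpoint rule.
#' @param background background intensity; `NULL` uses `median(frame)`.
#' @param step ray step in pixels.
#' @param max_px maximum ray length per side in pixels.
#' @return width in micrometres (or pixels when `pixel_pitch = 1`); 0 when
#'   the position lies on background.
#' @export
measureWidth <- function(frame, position, normal, pixel_pitch = 1,
                         threshold = NULL, background = NULL,
                         step = 0.25, max_px = 100) {
  if (is.null(background)) background <- stats::median(frame)
  v0 <- bilinearSample(frame, position[1], position[2])
  if (is.null(threshold)) threshold <- (v0 + background) / 2
  if (v0 >= threshold) return(0)
  tt <- seq(step, max_px, by = step)
  ray <- function(sgn) {
    ints <- bilinearSample(frame, position[1] + sgn * tt * normal[1],
                           position[2] + sgn * tt * normal[2])
    hit <- which(ints >= threshold)
    if (!length(hit)) return(max_px)
    tt[hit[1L]] - step / 2
  }
  (ray(+1) + ray(-1)) * pixel_pitch
}

#' Widths for every kept position of the active sections on one frame
#'
#' @inheritParams measureWidth
#' @param vss a \linkS4class{VeinSectionSet}.
#' @return data frame `section_id, pos_index, width_um`.
#' @export
measureFrameWidths <- function(frame, vss, pixel_pitch = 1,
                               background = NULL, step = 0.25,
                               max_px = 100) {
  act <- activeSections(vss)
  p <- vss@positions
  p <- p[p$keep & p$section_id %in% act, , drop = FALSE]
  if (!nrow(p))
    return(data.frame(section_id = integer(), pos_index = integer(),
                      width_um = numeric(), stringsAsFactors = FALSE))
  if (is.null(background)) background <- stats::median(frame)
  w <- vapply(seq_len(nrow(p)), function(i)
    measureWidth(frame, c(p$r[i], p$c[i]), c(p$nr[i], p$nc[i]),
                 pixel_pitch = pixel_pitch, background = background,
                 step = step, max_px = max_px), numeric(1))
  data.frame(section_id = p$section_id, pos_index = p$pos_index,
             width_um = w)
}

rejectSections <- function(vss, ids, reason) {
  if (!length(ids)) return(vss)
  hit <- vss@sections$section_id %in% ids & vss@sections$status == "active"
  vss@sections$status[hit] <- "rejected"
  vss@sections$reject_reason[hit] <- reason
  vss
}

#' Initial size filter
#'
#' Rejects sections whose mean measured width on the first frame exceeds
#' `max_mean_width_um` (default 1 mm, strict inequality): such measurements
#' do not represent real veins.
#'
#' @param vss a \linkS4class{VeinSectionSet}.
#' @param first_widths data frame `section_id, pos_index, width_um` from the
#'   first frame (see [measureFrameWidths()]).
#' @param max_mean_width_um rejection bound in micrometres.
#' @return updated \linkS4class{VeinSectionSet}.
#' @export
qcInitialSize <- function(vss, first_widths, max_mean_width_um = 1000) {
  m <- tapply(first_widths$width_um, first_widths$section_id, mean)
  bad <- as.integer(names(m)[m > max_mean_width_um])
  rejectSections(vss, bad, "size")
}

#' Positional consistency filter
#'
#' Checks the uniformity of the measurement positions within each section:
#' positions whose first-frame width falls outside the Tukey fences
#' (Q1 - 1.5 IQR, Q3 + 1.5 IQR) of the section's widths - widened by `tol`
#' to absorb pixel-quantisation jitter - are dropped; a section left with
#' fewer than `min_positions` is rejected. This removes positions that sit
#' on vein crossings or stray off the vein.
#'
#' @inheritParams qcInitialSize
#' @param widths data frame `section_id, pos_index, width_um`.
#' @param min_positions minimum surviving positions (default 4).
#' @param tol fence widening in the same units as the widths (default one
#'   pixel equivalent via `pixel_pitch`).
#' @param pixel_pitch micrometres per pixel, used for the default `tol`.
#' @return updated \linkS4class{VeinSectionSet} with `keep` flags updated.
#' @export
qcPositionalConsistency <- function(vss, widths, min_positions = 4,
                                    tol = NULL, pixel_pitch = 1) {
  if (is.null(tol)) tol <- pixel_pitch   # one pixel of slack
  bad_sections <- integer()
  for (sid in activeSections(vss)) {
    w <- widths[widths$section_id == sid, , drop = FALSE]
    if (!nrow(w)) next
    q <- stats::quantile(w$width_um, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr - tol
    hi <- q[2] + 1.5 * iqr + tol
    out <- w$width_um < lo | w$width_um > hi
    if (any(out)) {
      drop <- vss@positions$section_id == sid &
        vss@positions$pos_index %in% w$pos_index[out]
      vss@positions$keep[drop] <- FALSE
    }
    if (sum(vss@positions$keep[vss@positions$section_id == sid]) <
        min_positions)
      bad_sections <- c(bad_sections, sid)
  }
  rejectSections(vss, bad_sections, "consistency")
}

#' Median comparison filter
#'
#' Rejects sections whose median width is more than twice the overall median
#' (the median of the active sections' medians), iterated to a fixed point
#' so that re-running the filter on its own output changes nothing.
#'
#' @inheritParams qcPositionalConsistency
#' @return updated \linkS4class{VeinSectionSet}.
#' @export
qcMedianComparison <- function(vss, widths) {
  repeat {
    act <- activeSections(vss)
    if (length(act) < 2L) break
    keepPos <- vss@positions[vss@positions$keep, c("section_id", "pos_index")]
    w <- merge(widths, keepPos, by = c("section_id", "pos_index"))
    med <- tapply(w$width_um, w$section_id, stats::median)
    med <- med[names(med) %in% as.character(act)]
    overall <- stats::median(med)
    bad <- as.integer(names(med)[med > 2 * overall])
    if (!length(bad)) break
    vss <- rejectSections(vss, bad, "median")
  }
  vss
}

#' Colour-gradient (contrast) filter
#'
#' Rejects sections that fail to distinguish vein from background: the
#' absolute difference between the median intensity sampled at the section's
#' positions (on the vein) and the median of a local background ring sampled
#' along each normal just beyond the measured vein edge must be at least
#' `contrast_min` intensity units (strict `<` rejects).
#'
#' @inheritParams qcPositionalConsistency
#' @param frame denoised greyscale matrix.
#' @param contrast_min minimum vein/background intensity difference.
#' @param pixel_pitch micrometres per pixel (converts widths to px).
#' @param margin_px how far beyond the vein edge the background is sampled.
#' @return updated \linkS4class{VeinSectionSet}.
#' @export
qcColourGradient <- function(vss, frame, widths, contrast_min = 10,
                             pixel_pitch = 1, margin_px = 4) {
  bad <- integer()
  for (sid in activeSections(vss)) {
    p <- vss@positions[vss@positions$section_id == sid & vss@positions$keep,
                       , drop = FALSE]
    w <- widths[widths$section_id == sid, , drop = FALSE]
    if (!nrow(p) || !nrow(w)) next
    half_px <- stats::median(w$width_um) / pixel_pitch / 2
    vein <- stats::median(bilinearSample(frame, p$r, p$c))
    d <- half_px + margin_px
    bg <- stats::median(c(
      bilinearSample(frame, p$r + d * p$nr, p$c + d * p$nc),
      bilinearSample(frame, p$r - d * p$nr, p$c - d * p$nc)))
    if (abs(vein - bg) < contrast_min) bad <- c(bad, sid)
  }
  rejectSections(vss, bad, "contrast")
}

segmentMinDistance <- function(a, b) {
  # min distance between two 2D segments a = (p1, p2), b = (q1, q2)
  pd <- function(p, q1, q2) {
    v <- q2 - q1; w <- p - q1
    t <- if (sum(v * v) > 0) max(0, min(1, sum(w * v) / sum(v * v))) else 0
    sqrt(sum((q1 + t * v - p)^2))
  }
  segInt <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    s <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    t <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    s >= 0 && s <= 1 && t >= 0 && t <= 1
  }
  p1 <- a[1:2]; p2 <- a[3:4]; q1 <- b[1:2]; q2 <- b[3:4]
  if (segInt(p1, p2, q1, q2)) return(0)
  min(pd(p1, q1, q2), pd(p2, q1, q2), pd(q1, p1, p2), pd(q2, p1, p2))
}

#' Overlap elimination filter
#'
#' When the measurement-line footprints of two active sections intersect or
#' come within `min_sep_px`, the redundant one is discarded: the section
#' retaining more measurement positions survives, ties going to the lower
#' section id.
#'
#' @inheritParams qcPositionalConsistency
#' @param min_sep_px footprint separation below which sections overlap.
#' @return updated \linkS4class{VeinSectionSet}.
#' @export
qcOverlap <- function(vss, min_sep_px = 2) {
  act <- activeSections(vss)
  if (length(act) < 2L) return(vss)
  s <- vss@sections[vss@sections$section_id %in% act, , drop = FALSE]
  nkept <- vapply(s$section_id, function(id)
    sum(vss@positions$keep[vss@positions$section_id == id]), numeric(1))
  alive <- rep(TRUE, nrow(s))
  # rank: more kept positions first, then lower id
  o <- order(-nkept, s$section_id)
  for (i in seq_along(o)) {
    if (!alive[o[i]]) next
    for (k in seq_along(o)) {
      if (k <= i || !alive[o[k]]) next
      d <- segmentMinDistance(
        c(s$r1[o[i]], s$c1[o[i]], s$r2[o[i]], s$c2[o[i]]),
        c(s$r1[o[k]], s$c1[o[k]], s$r2[o[k]], s$c2[o[k]]))
      if (d < min_sep_px) alive[o[k]] <- FALSE
    }
  }
  rejectSections(vss, s$section_id[!alive], "overlap")
}

#' The five-stage quality-control cascade
#'
#' Applies, in order: initial size filter, positional consistency check,
#' median comparison, colour-gradient analysis and overlap elimination.
#' The cascade is idempotent: running it on its own output changes nothing.
#'
#' @inheritParams qcColourGradient
#' @param first_frame the denoised first frame of the vein series.
#' @param first_widths first-frame widths (computed if missing).
#' @param max_mean_width_um size-filter bound (default 1 mm).
#' @param contrast_min contrast-filter bound (intensity units).
#' @param min_sep_px overlap-filter separation (px).
#' @return updated \linkS4class{VeinSectionSet}.
#' @export
qcCascade <- function(vss, first_frame, first_widths = NULL,
                      pixel_pitch = 1, max_mean_width_um = 1000,
                      contrast_min = 10, min_sep_px = 2) {
  if (is.null(first_widths))
    first_widths <- measureFrameWidths(first_frame, vss,
                                       pixel_pitch = pixel_pitch)
  vss <- qcInitialSize(vss, first_widths, max_mean_width_um)
  vss <- qcPositionalConsistency(vss, first_widths,
                                 pixel_pitch = pixel_pitch)
  vss <- qcMedianComparison(vss, first_widths)
  vss <- qcColourGradient(vss, first_frame, first_widths,
                          contrast_min = contrast_min,
                          pixel_pitch = pixel_pitch)
  vss <- qcOverlap(vss, min_sep_px = min_sep_px)
  vss
}

#' Track section widths across a frame series
#'
#' Measures the width at every kept position of every active section in each
#' frame, at fixed image coordinates (the dish is static over the 1 h vein
#' recording), yielding the vein-diameter traces used for contraction
#' spectral analysis.
#'
#' @param series a \linkS4class{FrameSeries} (vein regime: 1 h at 4 s).
#' @param vss a QC-passed \linkS4class{VeinSectionSet}.
#' @param pixel_pitch micrometres per pixel; taken from the series when
#'   calibrated.
#' @param step,max_px ray-marching controls (see [measureWidth()]).
#' @return data frame `section_id, pos_index, t_seconds, width_um`.
#' @export
trackSections <- function(series, vss, pixel_pitch = NULL, step = 0.25,
                          max_px = 100) {
  if (is.null(pixel_pitch)) pixel_pitch <- pixelPitch(series)
  if (is.na(pixel_pitch)) pixel_pitch <- 1
  out <- vector("list", nFrames(series))
  for (t in seq_len(nFrames(series))) {
    w <- measureFrameWidths(series[[t]], vss, pixel_pitch = pixel_pitch,
                            step = step, max_px = max_px)
    w$t_seconds <- rep(timestamps(series)[t], nrow(w))
    out[[t]] <- w
  }
  res <- do.call(rbind, out)
  res[, c("section_id", "pos_index", "t_seconds", "width_um")]
}

#' Per-section mean-width traces
#'
#' Averages the per-position widths of each section at each timepoint,
#' giving one width-versus-time signal per section.
#'
#' @param widths long data frame from [trackSections()].
#' @return data frame `section_id, t_seconds, width_um`.
#' @export
sectionTraces <- function(widths) {
  agg <- stats::aggregate(width_um ~ section_id + t_seconds, data = widths,
                          FUN = mean)
  agg[order(agg$section_id, agg$t_seconds), ]
}
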