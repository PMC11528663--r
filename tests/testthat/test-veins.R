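crossingNumbers <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1] + 1L; j <- idx[k, 2] + 1L
    p <- c(pad[i - 1, j], pad[i - 1, j + 1], pad[i, j + 1],
           pad[i + 1, j + 1], pad[i + 1, j], pad[i + 1, j - 1],
           pad[i, j - 1], pad[i - 1, j - 1])
    sum(p == FALSE & c(p[-1], p[1]) == TRUE)
  }, numeric(1))
}

has2x2Block <- function(m) {
  any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1])
}

test_that("skeletonization thins to one-pixel medial lines", {
  bar <- matrix(FALSE, 40, 60); bar[18:22, 10:50] <- TRUE
  sk <- skeletonize(bar)
  # a single horizontal line: every column of the stroke has exactly 1 px
  cols <- colSums(sk)
  expect_true(all(cols[cols > 0] == 1))
  expect_equal(length(unique(which(sk, arr.ind = TRUE)[, 1])), 1L)

  disc <- matrix(FALSE, 50, 50)
  disc[(row(disc) - 25)^2 + (col(disc) - 25)^2 <= 15^2] <- TRUE
  skd <- skeletonize(disc)
  expect_lt(sum(skd), 20)           # near-point/short-line residue

  expect_equal(sum(skeletonize(matrix(FALSE, 10, 10))), 0)
})

test_that("skeletons of thick strokes have stroke width one", {
  for (w in c(3, 5, 9, 15)) {
    segs <- data.frame(r1 = 40, c1 = 15, r2 = 42, c2 = 105, width_px = w)
    fr <- myxometry:::compositeStrokes(c(80, 120), segs, antialias = FALSE)
    sk <- skeletonize(fr < 130)
    expect_false(has2x2Block(sk))
    expect_gt(sum(sk), 60)
  }
})

test_that("a Y junction skeletonizes to 3 endpoints and 1 branch point", {
  segs <- data.frame(r1 = 60, c1 = 60, r2 = c(20, 100, 100),
                     c2 = c(60, 25, 95), width_px = 9)
  fr <- myxometry:::compositeStrokes(c(120, 120), segs)
  sk <- skeletonize(fr < 130)
  cn <- crossingNumbers(sk)
  expect_equal(sum(cn == 1), 3L)
  expect_equal(sum(cn >= 3), 1L)
})

test_that("section detection recovers line geometry and obeys its gates", {
  # oblique single line: direction recovered within 2 degrees
  th <- 25 * pi / 180
  n <- 90
  sk <- matrix(FALSE, 120, 120)
  rr <- round(20 + (1:n) * sin(th)); cc <- round(15 + (1:n) * cos(th))
  sk[cbind(rr, cc)] <- TRUE
  vss <- detectSections(sk)
  s <- sections(vss)
  expect_gte(nrow(s), 1L)
  ang <- atan2(s$r2[1] - s$r1[1], s$c2[1] - s$c1[1]) %% pi
  d <- abs(ang - th)
  expect_lt(min(d, pi - d) * 180 / pi, 2)
  expect_gte(s$n_positions[1], 4L)
  # normals perpendicular to the detection line
  p <- positions(vss)
  u <- c(s$r2[1] - s$r1[1], s$c2[1] - s$c1[1])
  u <- u / sqrt(sum(u^2))
  expect_lt(abs(sum(u * c(p$nr[1], p$nc[1]))), sin(pi / 180))

  expect_warning(empty <- detectSections(matrix(FALSE, 30, 30)), "empty")
  expect_equal(nrow(sections(empty)), 0L)

  # min_line_length gate: 10-px run detectable, 8-px not
  g10 <- matrix(FALSE, 30, 30); g10[15, 6:15] <- TRUE
  g8 <- matrix(FALSE, 30, 30); g8[15, 6:13] <- TRUE
  expect_equal(nrow(sections(
    suppressWarnings(detectSections(g10, threshold = 5)))), 1L)
  expect_equal(nrow(sections(
    suppressWarnings(detectSections(g8, threshold = 5)))), 0L)
})

test_that("width measurement recovers drawn stroke widths", {
  segs <- data.frame(r1 = 40, c1 = 10, r2 = 40, c2 = 110, width_px = 20)
  fr <- myxometry:::compositeStrokes(c(80, 120), segs)
  # 10 um/px: drawn width 20 px = 200 um
  w <- measureWidth(fr, c(40, 60), c(1, 0), pixel_pitch = 10)
  expect_lt(abs(w - 200), 20)
  # constant width along the line: all positions agree within 2 px
  ws <- vapply(seq(30, 90, by = 10), function(cc)
    measureWidth(fr, c(40, cc), c(1, 0)), numeric(1))
  expect_lt(max(ws) - min(ws), 2)
  # background position yields zero width
  expect_equal(measureWidth(fr, c(10, 60), c(1, 0)), 0)
  expect_equal(measureWidth(matrix(200, 50, 50), c(25, 25), c(1, 0)), 0)
})

test_that("tracking a pulsating phantom follows the generator signal", {
  p <- makePulsatingSeries(dim = c(60, 120), n_frames = 150,
                           freq_hz = 0.010, width0_px = 10,
                           amplitude = 0.2, seed = 61, noise_sd = 1)
  f1 <- p$series[[1]]
  vss <- detectSections(skeletonize(segmentNetwork(f1, 79, 2)))
  vss <- qcCascade(vss, f1)
  expect_gte(length(activeSections(vss)), 1L)
  w <- trackSections(p$series, vss)
  expect_equal(length(unique(w$t_seconds)), 150L)
  tr <- sectionTraces(w)
  tr1 <- tr[tr$section_id == tr$section_id[1], ]
  expect_equal(nrow(tr1), 150L)
  expect_gt(cor(tr1$width_um, p$truth$width_px), 0.9)

  # a static phantom stays constant within one pixel equivalent
  ps <- makePulsatingSeries(dim = c(60, 120), n_frames = 10, amplitude = 0,
                            width0_px = 10)
  vss2 <- detectSections(skeletonize(segmentNetwork(ps$series[[1]], 79, 2)))
  vss2 <- qcCascade(vss2, ps$series[[1]])
  w2 <- sectionTraces(trackSections(ps$series, vss2))
  expect_lt(max(w2$width_um) - min(w2$width_um), 1)
})
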