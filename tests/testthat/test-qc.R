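test_that("initial size filter rejects over-1mm sections, boundary kept", {
  vss <- mkSectionSet(rows = c(20, 50, 80), npos = 4)
  w <- mkWidths(vss, list(1200, 300, 1000))   # um
  out <- qcInitialSize(vss, w)
  expect_equal(statusOf(out, 1), "rejected")
  expect_equal(reasonOf(out, 1), "size")
  expect_equal(statusOf(out, 2), "active")
  expect_equal(statusOf(out, 3), "active")    # exactly 1 mm: strict >
})

test_that("positional consistency drops outlier positions then re-counts", {
  # one gross outlier among four positions: dropped, then too few remain
  vss <- mkSectionSet(rows = 20, npos = 4)
  w <- mkWidths(vss, list(c(10, 10, 10, 40)))
  out <- qcPositionalConsistency(vss, w, pixel_pitch = 1)
  expect_equal(statusOf(out, 1), "rejected")
  expect_equal(reasonOf(out, 1), "consistency")

  # small quantisation jitter is tolerated
  vss2 <- mkSectionSet(rows = 20, npos = 5)
  w2 <- mkWidths(vss2, list(c(10, 10, 11, 10, 10)))
  out2 <- qcPositionalConsistency(vss2, w2, pixel_pitch = 1)
  expect_equal(statusOf(out2, 1), "active")
  expect_true(all(positions(out2)$keep))

  # outlier among five: dropped, four remain, section stays active
  w3 <- mkWidths(vss2, list(c(10, 10, 10, 10, 40)))
  out3 <- qcPositionalConsistency(vss2, w3, pixel_pitch = 1)
  expect_equal(statusOf(out3, 1), "active")
  expect_equal(sum(positions(out3)$keep), 4L)
})

test_that("median comparison excludes sections above twice the overall", {
  vss <- mkSectionSet(rows = c(20, 50, 80), npos = 4)
  w <- mkWidths(vss, list(10, 10, 25))
  out <- qcMedianComparison(vss, w)
  expect_equal(statusOf(out, 3), "rejected")
  expect_equal(reasonOf(out, 3), "median")
  expect_equal(statusOf(out, 1), "active")

  # all equal: none rejected
  we <- mkWidths(vss, list(10, 10, 10))
  oute <- qcMedianComparison(vss, we)
  expect_true(all(sections(oute)$status == "active"))

  # (10, 20): 20 <= 2 x 15, none rejected
  vss2 <- mkSectionSet(rows = c(20, 60), npos = 4)
  w2 <- mkWidths(vss2, list(10, 20))
  out2 <- qcMedianComparison(vss2, w2)
  expect_true(all(sections(out2)$status == "active"))
})

test_that("colour-gradient filter demands vein/background contrast", {
  # strong contrast: dark stroke on bright field
  segs <- data.frame(r1 = 30, c1 = 10, r2 = 30, c2 = 110, width_px = 10)
  fr <- myxometry:::compositeStrokes(c(60, 120), segs, fg = 60, bg = 200)
  vss <- mkSectionSet(rows = 30, npos = 5, c1 = 30, c2 = 90)
  w <- mkWidths(vss, list(10))
  out <- qcColourGradient(vss, fr, w, pixel_pitch = 1)
  expect_equal(statusOf(out, 1), "active")

  # near-zero contrast: rejected
  fr2 <- myxometry:::compositeStrokes(c(60, 120), segs, fg = 128, bg = 130)
  out2 <- qcColourGradient(vss, fr2, w, pixel_pitch = 1)
  expect_equal(statusOf(out2, 1), "rejected")
  expect_equal(reasonOf(out2, 1), "contrast")

  # exactly at the threshold: strict "<" keeps nothing below it
  fr3 <- myxometry:::compositeStrokes(c(60, 120), segs, fg = 120,
                                      bg = 130, antialias = FALSE)
  out3 <- qcColourGradient(vss, fr3, w, pixel_pitch = 1, contrast_min = 10)
  expect_equal(statusOf(out3, 1), "active")
})

test_that("overlap elimination keeps one of each redundant pair", {
  # exact duplicate
  vss <- mkSectionSet(rows = c(20, 20), npos = 4)
  out <- qcOverlap(vss)
  expect_equal(sum(sections(out)$status == "active"), 1L)
  expect_equal(activeSections(out), 1L)    # tie broken by lower id

  # disjoint sections both survive
  vss2 <- mkSectionSet(rows = c(20, 60), npos = 4)
  out2 <- qcOverlap(vss2)
  expect_equal(sum(sections(out2)$status == "active"), 2L)

  # crossing X: exactly one survives
  segs <- list(c(10, 10, 50, 50), c(50, 10, 10, 50))
  vssx <- myxometry:::buildSectionSet(segs, spacing = 10)
  outx <- qcOverlap(vssx)
  expect_equal(sum(sections(outx)$status == "active"), 1L)
})

test_that("the QC cascade is ordered and idempotent", {
  p <- makePulsatingSeries(dim = c(80, 120), n_frames = 1, amplitude = 0,
                           n_veins = 2, width0_px = c(8, 12))
  f1 <- p$series[[1]]
  vss <- detectSections(skeletonize(segmentNetwork(f1, 79, 2)))
  w <- measureFrameWidths(f1, vss)
  once <- qcCascade(vss, f1, w)
  twice <- qcCascade(once, f1, measureFrameWidths(f1, once))
  expect_identical(sections(twice), sections(once))
  expect_identical(positions(twice), positions(once))
  expect_gte(length(activeSections(once)), 1L)
})
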