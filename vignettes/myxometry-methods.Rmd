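---
title: "Quantifying plasmodial networks: methods and design choices"
author: "myxometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasmodial networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxometry)
```

## The measurement problem

A *Physarum polycephalum* plasmodium is a single giant cell organised as a
network of tubular veins. Photographed from above at regular intervals in a
Petri dish, two kinds of information are accessible without any invasive or
expensive instrumentation:

* **Macroscopic growth dynamics** over a 24 h recording at one frame per
  minute: how much area the organism covers, how much of the dish it has
  ever visited, and how structurally complex its network is.
* **Vein-level physiology** over a subsequent 1 h recording at one frame
  per 4 s: the diameter of individual veins and the slow (~10 mHz)
  peristaltic contraction rhythm that drives shuttle streaming, visible as
  an oscillation of vein width.

myxometry implements both analysis chains, plus an estimator that combines
them into a total network volume with geometric error bounds, and a seeded
phantom-image generator so that every stage can be validated against known
ground truth without any recordings.

## Image preparation

Frames are loaded as 8-bit greyscale (RGB is reduced with the standard
luminance weights 0.299/0.587/0.114; the capture pipeline this emulates
records in greyscale, so the exact weights are a free choice).
Timestamps come from the configured capture interval rather than file
metadata, which keeps reloaded series reproducible.

Sensor noise is suppressed with non-local-means denoising
(`denoiseFrame()`, filter strength 8, 5 px template window, 21 px search
window). The dish interior is isolated with a circle Hough transform on the
Sobel edge map (`detectDishROI()`): the highest-voted circle within the
configured radius bounds wins, ties going to the candidate nearest the
frame centre, and the winner must additionally be supported by rim edges
along at least half of its circumference — a guard that turns "no dish in
the admissible radius range" into an explicit error instead of a spurious
circle. The ROI is detected once, on the first frame, and reused: the dish
does not move. Pixels outside the ROI are filled with 255 (bright-agar
convention) so that inverse thresholding can never label them organism.

## Growth, exploration and the dose-response summary

Segmentation uses Gaussian-weighted local-mean thresholding in
inverse-binary mode (`segmentNetwork()`): a pixel is organism iff its
intensity falls below the local weighted mean minus an offset. Defaults are
a 71 px window with offset 4 for the growth regime and a 79 px window
(midpoint of the 69–91 range appropriate for the macro optics) with offset
2 for the vein regime. Two well-known properties of local thresholding
matter for interpretation: solid objects much larger than the window
hollow out (only edges are detected), and bright objects cast a faint
"halo" of marked background just outside themselves. Neither affects
vein-like structures, which is what the method is tuned for; the phantom
fixtures are sized accordingly.

From the per-frame masks:

* `areaSeries()` converts foreground pixel counts to mm² via the pixel
  pitch calibrated from a reference of known size (e.g. the 92 mm dish
  diameter), and also carries the baseline-subtracted series (area minus
  the area at t₀) used for plotting growth increments.
* the **growth rate** is (A~t24~ − A~t0~)/A~t0~ on the *raw* areas — the
  baseline-subtracted series is zero at t₀ and would make the ratio
  undefined. A~t24~ is the frame nearest 24 h within one capture interval.
* `explorationSeries()` accumulates the running union of occupied pixels;
  the **exploration rate** is EA~t24~/24 in mm²/h. The union is monotone
  by construction, and the initial inoculum disc counts toward both area
  and explored area (no carve-out).
* masks are not hole-filled: veins enclose background windows, and the
  pixel count of the thresholded image is the quantity of interest.

For dose-response experiments, `growthInhibition()` returns the normalised
difference (Area~c~ − mean(Area~c0~))/mean(Area~c0~), which is negative
under inhibition; the conventional positive "growth inhibition" magnitude
is its negation, and both signs are available to the caller since plotted
conventions differ. `fitDoseResponse()` fits a least-squares polynomial
(default degree 3) and returns per-concentration means and standard
deviations for error bars.

## Fractal complexity

`fractalDimension()` estimates the box-counting dimension: the negative
slope of log(occupied boxes) against log(box size). Design choices the
method itself does not fix:

* box sizes default to descending powers of two in [2, min(H, W)/4];
* grids are anchored at the mask's bounding-box corner, which makes the
  count invariant to translation and background padding;
* a single grid offset is used for determinism (offset averaging changes
  D by less than the fit noise on our calibration patterns);
* the R² of the log–log fit is always reported, so a poor scaling regime
  is visible rather than silent.

The estimator is calibrated on exact rasterisations with known dimension:
a straight line (D = 1), a filled square (D = 2) and a depth-7 Sierpinski
triangle (D = log 3/log 2 ≈ 1.585), all produced by
`makeFractalPattern()`. `fractalSeries()` evaluates D on the mask nearest
each point of a 10-minute grid, the standard thinning of a
one-frame-per-minute recording, and reuses the growth segmentation masks.

## Vein morphometry

The first vein-regime frame is thresholded and thinned to a one-pixel
skeleton (`skeletonize()`, Zhang–Suen iterative thinning, topology
preserving). Straight measurement sections are found on the skeleton with
a Hough transform (`detectSections()`; accumulator resolution 1 px and
1°, vote threshold 25, minimum length 10 px). The implementation is a
deterministic accumulator-peak/collinear-run extraction rather than the
randomized progressive variant: section placement is then exactly
reproducible for a given frame, with the same parameter semantics. A
segment's length is its pixel count, and each section carries at least
four measurement positions, spaced every 5 px along the detection line,
with the unit normal attached.

`measureWidth()` marches outward from each position along both directions
of the normal in 0.25 px steps with bilinear intensity sampling, stopping
at the first sample brighter than the midpoint between the on-vein
intensity and the background level (frame median by default); the width is
the sum of the two ray lengths times the pixel pitch. On phantoms with
drawn widths of 5–30 px this recovers widths with a mean absolute error of
about a quarter pixel.

### The quality-control cascade

Five filters run in a fixed order (size → positional consistency → median
comparison → colour gradient → overlap), each recording its rejection
reason; the cascade is idempotent, so re-running it on its own output
changes nothing:

1. **Initial size**: sections whose mean first-frame width exceeds 1 mm
   (strict) are not veins.
2. **Positional consistency**: within a section, positions outside the
   Tukey fences (Q1 − 1.5 IQR, Q3 + 1.5 IQR) of the section's widths are
   dropped; fewer than four survivors rejects the section. The fences are
   widened by one pixel-equivalent: measured widths are quantised at the
   pixel scale, and with type-7 quantiles an unwidened fence of width zero
   (IQR = 0) would reject positions that differ from their neighbours by
   a single pixel of jitter.
3. **Median comparison**: sections whose median width exceeds twice the
   median of the active sections' medians are rejected; the rule is
   iterated to a fixed point so the filter is idempotent.
4. **Colour gradient**: the median on-vein intensity must differ from a
   local background ring (sampled along each normal just beyond the
   measured vein edge) by at least 10 intensity units; equality at the
   threshold keeps the section.
5. **Overlap**: when two sections' measurement lines intersect or come
   within 2 px, the one retaining more positions survives (ties: lower
   section id).

Positions that survive QC are then measured in **every** frame at fixed
image coordinates (`trackSections()`) — the dish is static over the hour —
yielding one width trace per position, averaged per section by
`sectionTraces()`.

## Contraction frequency

Width traces are denoised in the frequency domain (`iqrNoiseFilter()`):
PSD bins at or below the Q3 + 1.5 IQR noise border are zeroed
(symmetrically over conjugate bins, so the inverse transform stays real;
the DC bin is always kept). The gate is computed on the full-trace PSD,
matching the processing order of the denoise-then-Welch chain; a flag can
move it inside the slices.

Because the contraction rhythm drifts over an hour, the spectral estimate
uses Welch's method (`welchPsd()`): slices of 256 samples (~17 min at
0.25 Hz — at least two cycles of the slowest physiological rhythm, the
shortest slice that still resolves ~8 mHz) with 90 % overlap, each slice
mean-removed and Hanning-windowed. Per slice, the frequency is the
power-weighted mean over the seven bins centred on the spectral peak
(DC excluded),

$$\hat f = \frac{\sum_{i=j-3}^{j+3} P_i \, i \, F_s/N}{\sum_{i=j-3}^{j+3} P_i},$$

which interpolates between bins: on off-bin-centre sinusoids its RMSE is
roughly forty times smaller than the argmax bin's. The section estimate is
the mean over slices. Periodogram scaling (window-power normalisation)
cancels in this ratio, so the estimator is scale-free.

A trace whose full-spectrum peak does not exceed three times the IQR noise
border is flagged low-confidence: for a featureless (white-noise) trace the
*extreme* periodogram bin always sits somewhat above the border — the
border is a per-bin statistic — so a margin factor is needed to separate
genuine oscillations from noise extremes; three is conservative in both
directions on simulated traces. Finally `organismAverage()` applies the
concluding 1.5 IQR outlier check across sections and reports the
organism-level mean ± σ, since the comparison of interest is between
organisms, not between positions.

## Network volume

With hundreds of vein diameters pooled (as per-position time-means over
the hour — the stable choice; instantaneous widths oscillate by design),
`diameterDistribution()` bins them into 50 equal-width intervals between
the minimum and maximum, and each interval contributes a cylinder:

* stepsize = Δdiameter / 50, proportion *p* = fraction of measurements in
  the interval;
* length *l* = A · p / 2r, where A is the 24 h raw covered area (the raw
  area, not the baseline-subtracted series: the physical network includes
  the inoculum) and 2r the interval centre;
* volume = Σ π r² l, and the **normalised volume** (volume / A) is an
  effective mean network thickness in mm. For a uniform cylinder these
  relations are exact identities (l = L, volume = πr²L, normalised =
  πr/2), which is how the chain is validated.

Veins need not be circular in cross-section. If the true section is a
circular segment (angle α missing) the relative error of the circular
assumption is ε~S~ = (α − sin α)/(2π − (α − sin α)); if it is an ellipse
flattened by x, ε~E~ = x/(2r − x). Both vanish in the circular limit,
equal 1 at α = π and x = r, and increase strictly with their parameter.
`estimateVolume()` reports the implied worst-case interval
[total/(1 + ε~max~), total] for user-chosen α and x, presenting ε as a
range rather than applying a correction.

## The phantom generator

`makeDish()`, `makeGrowingDiskSeries()`, `makeVeinNetwork()`,
`makePulsatingSeries()` and `makeFractalPattern()` emulate, respectively:
the bright agar field inside a dark dish rim; a growing or translating
dark disc; a static network of dark strokes with controllable widths;
horizontal veins whose widths oscillate sinusoidally (or chirp) at a
configurable frequency; and exact rasterisations of known fractal
dimension. Every phantom is bit-reproducible from its parameters and seed
and is emitted together with the ground truth needed to oracle the
analysis (analytic areas, per-stroke geometry, per-frame widths, the
modulation parameters).

Edges are anti-aliased by default — the one-pixel greyscale ramp is what
the ray-casting stop rule sees on real optics. A hard-edge mode exists for
exact-count tests; in that mode the doubling-disc fixture solves the end
radius so that the rasterised pixel count doubles exactly, removing
boundary-rasterisation jitter from the growth-rate oracle.

What the phantoms deliberately do **not** model: protoplasmic texture and
internal intensity gradients, optical vignetting, focus drift, organism
motion during the vein hour, and any biophysics (flow, chemotaxis,
fronts). Passing tests therefore demonstrate the correctness of the
measurement chain on controlled geometry, not robustness to every
real-world artefact; parameters exposed in the configuration are the
intended adjustment surface for real recordings.

## Numerical choices and degenerate inputs

* Adaptive-threshold windows are clamped to the frame when a frame is
  smaller than the configured window.
* Zero-contrast frames segment to empty masks; empty masks skeletonize to
  empty skeletons; an empty skeleton yields an empty section list with a
  warning, not an error.
* An all-equal diameter sample degenerates to a single interval with a
  warning (the stepsize formula would divide by zero).
* A trace shorter than 16 samples cannot be IQR-filtered; a Welch segment
  longer than the trace is an error.
* Strict inequalities follow the filter definitions: "over 1 mm" and
  "twice the overall median" reject strictly above the bound; the
  contrast rule rejects strictly below its minimum.
* Ties in the Hough accumulators resolve deterministically (highest vote,
  then proximity to frame centre for circles; fixed scan order for
  lines), so identical inputs always yield identical sections.

## Problem sizes used by the tests

The test-suite and acceptance fixtures run at desk scale, chosen to keep
the geometry in the regimes the methods assume: dish phantoms of 240²
px with rim radii 70–95 px; growth series of 25 frames at 120² px;
pulsating series of 900 frames (the full 1 h at 0.25 Hz) at 120×160 px;
width-recovery networks of 6 strokes × 12 seeds (72 sections, widths
100–600 µm at 20 µm/px); 100 seeded sinusoids for the estimator-RMSE
comparison; 1000-point grids for the error-bound monotonicity checks.

## Known limitations

* Measurement positions are fixed in image coordinates over the vein
  hour; a drifting organism would need registration first.
* The width stop rule assumes dark veins on a brighter background with a
  monotone edge ramp; specular highlights inside a vein would terminate a
  ray early.
* The volume model treats intervals as independent cylinders; junction
  volumes are neither added nor subtracted.
* Box-counting D is reported for masks of any size, but fewer than three
  usable box scales is an error rather than an extrapolation.
* The dose-response helper fits an unweighted polynomial; replicate
  variance is reported but not used as weights.
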