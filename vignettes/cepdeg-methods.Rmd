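---
title: "Methods: quantifying CEP dendrite degeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying CEP dendrite degeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cepdeg)
```

## Scope and assumptions

`cepdeg` quantifies degeneration of the four cephalic (CEP) dopaminergic
neurons in *C. elegans* from 2-D maximum-intensity projections of
GFP-labelled heads. The pipeline assumes:

* exactly one worm in the frame, oriented so that all four CEP dendrites
  are visible (overlapping dendrites are scored as breaks);
* the cell bodies are the brightest extended structures in the frame
  (true for `dat-1p::GFP`-type reporters, where soma fluorescence far
  exceeds dendrite fluorescence);
* the projection covers the whole neuron in z — gaps caused by
  undersampled stacks are indistinguishable from genuine breaks;
* the camera pixel size (µm/px) supplied by the user is correct. Every
  structuring element, separation threshold and minimum size in the
  algorithm is stated in µm and converted through this one number, which
  is the entire mechanism behind cross-setup portability. Nothing else is
  retuned between a 63×/0.1 µm px camera and a 40×/0.2 µm px camera.

A forward-only tracking model is used deliberately: each dendrite is
represented as a function x(y). Dendrites that reverse direction (kinks
of 90° or more) cannot be represented and are smoothed/interpolated
through; this is a documented limitation, not a failure mode.

## Stage by stage

### Cropping

The global contrast stretch maps the 0.5th–99.9th intensity percentiles
onto the full bit range. The upper anchor is deliberately a *percentile*,
not the maximum, so isolated hot pixels cannot compress the scale; after
the stretch, the brightest real structure sits at full range by
construction. Cell bodies are then segmented at a fixed fraction (0.8) of
the full stretched range. We use an intensity-relative threshold rather
than a pixel-count percentile because a count percentile depends on how
much empty background happens to be in the frame — larger or rotated
frames would silently change the threshold, while a fraction of the
anchored range does not. Candidate somas must exceed 4 µm² in area *and*
1.5 µm in minor-axis width; the width test keeps bright ridge crests of
dendrites from posing as cell bodies.

Surviving soma components are grouped by single linkage; clusters farther
than 25 µm apart mean several worms in the frame, which is an error by
contract. The image is rotated so the line through the soma centroids is
horizontal (principal axis of the soma mask when fewer than two
centroids survive), reported modulo 180°; whether the dendrites lie above
or below the somas is settled afterwards by side selection, which
compares the two halves on Otsu-binarized component statistics: a half
scores one point per component at least 10 µm long, within 30° of
vertical, with circularity ≤ 0.5; ties break on summed major-axis length.
The winning half is flipped if necessary so the proximal edge is the
bottom edge — every downstream "distance from the cell body" is defined
against this canonical orientation. Finally, components touching the
lateral borders and residual soma-like fragments (circularity > 0.8 *and*
area > 4 µm²) are removed and the crop is tightened with a 2 µm margin.

### Enhancement and feature detection

Feature detection works on an enhanced copy of the ROI: CLAHE (clip
limit 2, ~16 µm tiles) blended with the original image with weight
1/(1 + noise/0.02), so noisy images are enhanced more gently — blending
at a fixed clip limit has the same effect as lowering the limit but
avoids the pathological slow regime of clip-redistribution near limit 1;
then white top-hat background subtraction with a 2 µm disc (removes soma
halo and illumination bias, preserves bleb-sized structures); then 4×
bilinear upsampling, which supplies subpixel resolution for the
morphological steps. The background subtraction runs at native ROI scale
before the resize: the two orders are equivalent to within interpolation
error, and the native-scale disc is 16× cheaper. The noise level recorded
for later thresholds is the scaled median absolute deviation of sub-Otsu
(background) pixels of the enhanced image.

Dendrite foreground is `Otsu + k·noise` with k = 1 — the one knob
implementing "noisier image, higher threshold". The feature primitive is
a single-pass **horizontal erosion** with a 1.4 µm line (about twice the
nominal dendrite width): anything not wider than a dendrite disappears,
and surviving clusters above 0.25 µm² seed features. Seeds are dilated by
0.3 µm and evolved for 60 iterations of morphological Chan-Vese
(two-phase ACWE: boundary pixels flip toward the nearer of the
inside/outside means, with an alternating opening/closing smoothing
step) on a window padded 3 µm around the seed. Implementation detail
that matters: after evolution the region receives one horizontal opening
with the same 1.4 µm element, removing contour creep along the bright
but thin dendrite ridge — without it, blebs a few µm apart merge through
the ridge into one feature. Refined regions are fused only if they
overlap by more than 30 % of the smaller region.

Descriptors are computed on the converged region: area and extent from
pixel counts (so a filled axis-aligned rectangle has extent exactly 1, a
thin cross near 0), perimeter as the length of the sub-pixel 0.5-level
contour (unbiased on discrete discs, unlike boundary-pixel counting),
circularity 4πA/P² clipped to [0, 1.05], min/max caliper by rotating
calipers on the contour's convex hull, eccentricity from second central
moments with the 1/12 single-pixel term. Feature intensities are sampled
bilinearly from the *original, un-enhanced* ROI in native units:
enhancement is image-adaptive, so intensities measured on enhanced
pixels would not be comparable across images.

### Tracking

Per row (top/distal first), up to four local maxima are accepted if they
clear a prominence floor of 2× the noise level *and* the dendrite
threshold (Otsu + k·noise), with pairwise separation ≥ 1 µm. The height
requirement is load-bearing: prominence alone collapses to zero on
near-noiseless images and lets background ripples seed marks in empty
margin rows. Accepted points are dilated 0.1 µm horizontally (absorbing
single-pixel x-jitter), closed vertically with a 5 µm element — long
enough to bridge detection dropouts, and deliberately allowed to bridge
*true* breaks, because tracks must span breaks for break detection to
measure them later — and skeletonized by per-row run centres, which is
exact for near-vertical one-pixel ridges.

Binning walks rows distally→proximally keeping an exponential moving
average (weight 0.1) of each dendrite's x; a point joins the nearest
average within a 2 µm gate, duplicates resolve to the closer point, ties
to the lower index, and new dendrites may only be seeded in the first
25 % of rows while fewer than four exist. Tracks are interpolated across
interior gaps, smoothed with a 2 µm moving average and re-indexed left to
right. Detected vs interpolated rows remain flagged.

### Breaks, matching, report

Break detection re-binarizes the enhanced image at half the feature
threshold — a permissive level on purpose, because the question is "is
there *any* dendrite signal here", and a dim-but-intact dendrite must not
be scored broken. Each track row probes this mask within ±0.5 µm; runs of
misses at least 0.5 µm long become breaks (shorter dropouts are sensor
noise at all tested pixel sizes). Lengths use a pixel-extent convention
(a run of n rows spans n·Δy), and the dendrite length is the track's
polyline arc length plus one row extent, so
`remaining + total_break = length` holds exactly.

Features match to the track minimizing horizontal distance at the
feature's row, within a 2 µm gate; unmatched features are excluded from
per-dendrite aggregates. The normalized feature location runs from 0 at
the proximal (cell-body) end to 1 at the distal tip. Feature aggregates
are null-coded (`NA`), not zero, when no feature matched — a dendrite
with no blebs has no mean bleb area.

### Categorical score

The 0–4 score reproduces the manual scale with breakage taking
precedence: < 50 % remaining → 4; 50–85 % (inclusive) → 3; otherwise 0,
1 or 2 for 0, 1–4, and ≥ 5 blebs. Two boundary cases are not fixed by
the published wording, which says "less than 5 blebs (1), more than 5
blebs (2)" and leaves both 85 % and exactly 5 blebs open: this package
maps 85 % to score 3 and 5 blebs to score 2, keeping the function total.
Both choices are asserted in tests so they cannot drift silently.

## The phantom generator

`render_phantom()` draws the validation scenes: four soft-edged soma
discs at the proximal edge, four Gaussian-profile ridges (FWHM =
`dendrite_width`, default 0.7 µm) along gently curved centerlines, blebs
as brighter isotropic Gaussian blobs (default 1.5× dendrite peak) on the
centerline, breaks as zeroed arc spans, a linear background ramp,
Poisson shot noise and Gaussian read noise, quantized to 8 or 16 bits.
Rotation is applied to the *geometry* before rasterization, so rotated
scenes carry no interpolation artifacts and truth coordinates are exact.
Rendering is bit-identical for a fixed spec and seed.

Default study conditions: 40 µm dendrites spaced 4 µm, 1 µm curvature
amplitude, 3 µm somas, 2 % read noise with an 800-photon shot budget,
0.1 µm/px/16-bit (the high-magnification setup) with 0.2 µm/px and 8-bit
variants in the catalogue. The fixture catalogue (`phantom_suite()`)
covers every score bin, ±30° rotations, both bit depths and both pixel
sizes; truth values are placed robustly *inside* score bins (e.g. an
8 µm break on a 40 µm dendrite → 80 % remaining, not 6 µm → 85.03 %,
which would sit on the bin edge and make the expected score
ill-conditioned).

What the phantoms do not emulate: gut autofluorescence, overlapping or
crossing dendrites, soma-shape variability, depth-dependent blur, or
uneven labelling. Passing the suite therefore demonstrates the
pipeline's correctness on its stated geometry — four separated,
near-vertical dendrites — and its physical-unit invariances; it does not
certify performance on pathological real-world frames, which the error
checks are designed to reject rather than mis-score.

## Numerical choices and degenerate inputs

* Blank frames (zero variance), unreadable files and RGB inputs are
  rejected at load; RGB is refused rather than averaged because channel
  choice is a scientific decision.
* A track with fewer than 2 detected rows is dropped; a dendrite shorter
  than 5 µm yields a report flagged `unreliable`.
* An empty break mask means 0 % remaining, not an error.
* Chan-Vese seeds whose region collapses are dropped with a note.
* Ties (equidistant point-to-track, feature-to-track) resolve to the
  lower dendrite index, making runs deterministic.
* All tests and the acceptance script run single-threaded with fixed
  seeds; problem sizes (610×280 px phantoms, 100-phantom oracle sweeps,
  1000-replicate null calibration at n = 30/group) were chosen so the
  full suite completes in a few minutes on a laptop-class machine.

## Cohort statistics

Each dendrite is one observation (N = 1 per dendrite). z-scores use
**control-SD** standardization, `z = (mean_t − mean_c)/sd_c`: the
treatment effect is expressed in units of control variability, with sign
carrying direction. A pooled SD would be the conventional alternative;
control-SD is the reading most consistent with "compared to their
control", and the choice is recorded in the output metadata
(`attr(x, "standardization")`). Metrics with zero control variance
null-code to `NA` with a warning. `cohort_anova()` fits one-way ANOVA
per metric; Bonferroni corrects all pairwise comparisons
(`p_adj = min(1, m·p)`), Dunnett compares each group to the control via
the multivariate-t formulation (multcomp). Groups with fewer than two
observations are excluded with a warning. Type-I calibration of the
corrected flags is asserted by simulation in the test suite.

## Known limitations

Forward-only tracking (≥ 90° kinks smoothed through); one worm per
frame; four visible dendrites assumed (overlaps score as breaks); breaks
at the extreme distal tip shorten the track instead of registering as
breaks; feature sub-types (bleb vs swelling vs fragment) are not
distinguished.
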