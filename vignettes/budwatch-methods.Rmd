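---
title: "Methods: segmenting, tracking and measuring budding cells with budwatch"
author: "budwatch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting, tracking and measuring budding cells with budwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budwatch)
```

## The problem

Budding yeast imaged label-free in trapped microfluidic devices poses a
segmentation problem that most cell-segmentation tools sidestep: a growing
bud genuinely *overlaps* its mother and often its sister in the 2-D
projection, because the bud grows out of the mother's surface and the
microscope integrates over depth. Per-pixel instance labelling cannot
represent two cells on one pixel, so any method built on a single label
image must merge or truncate overlapping cells — and the bud, the cell
whose growth rate carries most of the physiological signal, is exactly the
cell that overlaps.

`budwatch` addresses this with a semantic-map formulation. A small
multi-target U-net (or, for testing, an oracle that produces the same maps
from ground truth) predicts eight per-pixel maps from a bright-field
Z-stack:

1. three **eroded cell interiors**, stratified by cell size (S/M/L),
2. three **cell edges**, stratified the same way,
3. all **pairwise overlaps** between cells,
4. the **bud necks** joining mothers to buds.

Because cells of similar size rarely overlap once the population is split
by size, and because each interior is morphologically eroded, the
size-stratified interior maps contain one connected component per cell.
Instances are recovered by reversing the erosion and refining each outline
against the edge map with a star-convex radial spline; overlapping masks
are recovered per cell, not per pixel.

Downstream, two gradient-boosted pairwise classifiers track cells through
time, a third accumulates mother–bud pairing evidence, and volumes from
the conical method are smoothed with Gaussian processes whose derivative
posteriors give instantaneous single-cell growth rates, a cytokinesis-time
heuristic and a real-time "escape fraction" statistic for feedback
control of experiments.

## The synthetic benchmark

Everything in the package is testable without external data because the
`synthetic` module generates trapped-colony movies with exhaustive ground
truth: overlapping masks, track labels, lineage, cytokinesis times and
true volume trajectories.

The generator's defaults are the study conditions used throughout the
tests and the acceptance script, chosen once to be realistic for trapped
budding yeast and not revisited:

* 96 x 96 px at 0.263 um/px, five Z sections 0.6 um apart, frames every
  5 min — a typical trapped-yeast acquisition geometry;
* trapped mothers of equivalent radius 9–13 px (2.4–3.4 um, i.e. roughly
  55–160 um^3), fixed in place; cells are ellipses with axis ratio at most
  1.25 (buds 1.15), so every outline is comfortably star-convex;
* buds nucleate on the mother boundary with a per-bud mother-overlap
  fraction drawn from 0.08–0.40 of bud area, and `overlapBias` steers the
  placement angle toward neighbouring cells;
* bud volume starts at 4 um^3 and grows linearly at 10–30 um^3/h (under
  the exponential law the same field is read as a specific rate in 1/h,
  so that V(t+dt)/V(t) = exp(g dt) exactly);
* cytokinesis occurs when the bud reaches 45–60% of its mother's volume;
  the daughter then grows at 15% of its bud rate, the mother re-buds after
  a two-frame refractory period;
* attached buds pivot about their mother with probability `pivotProb` per
  frame; daughters are washed out with probability `washoutProb`
  (mothers are trapped and never leave);
* the projected outline of a cell is the ellipse whose equivalent radius
  matches the sphere-equivalent radius of its true volume, so area tracks
  volume monotonically.

Rendering is deliberately schematic — bright interior, dark rim, per-Z
Gaussian defocus that grows with the distance from the cell's focal plane,
additive noise — not an optics simulation. Small buds are assigned focal
planes away from the central section, which reproduces the practically
important fact that a small bud may be nearly invisible in one section and
sharp in another. What passing tests on this benchmark do *not* show is
robustness to real bright-field texture: traps, debris, halo artefacts and
focus drift are absent, so measured accuracies are upper bounds with
respect to image realism, while the geometry of the task (overlap,
pivoting, washout) is faithfully exercised.

## Target generation

Size categories are half-open area intervals [0, b1), [b1, b2), [b2, Inf)
on the full (un-eroded) mask area. The two thresholds are set by a grid
search over area quantiles that minimises the total within-category
pairwise overlap area, with ties broken toward the area terciles; with no
overlaps anywhere the terciles are returned. Erosion depths default to 1,
2 and 3 px for S, M and L.

Erosion and dilation use the exact Euclidean disc via distance maps.
Two lattice subtleties matter:

* A Euclidean erosion of depth 1 keeps boundary pixels whose only
  background neighbours are diagonal (distance sqrt(2)), which would let a
  cell's interior and edge targets intersect. Target erosion therefore
  always removes the 8-connected outline as well; per cell, the depth is
  eased in 0.5 px steps until at least `minSeedArea` (default 5 px^2)
  pixels survive, so no cell vanishes.
* Because outline removal dominates at depth 1, the *effective* erosion
  radius is about 1.7 px; `reverseErosion` dilates by
  max(depth, 1.7) so that erode-then-reverse is close to the identity on
  convex cells.

The overlap channel is the union of all pairwise mask intersections. The
synthetic bud-neck channel is the band of pixels within 1.5 px of both
masks of each mother–bud pair (curated data would provide necks as
annotations instead).

## Instance segmentation

Seeds are 4-connected components of each thresholded interior channel
(`pInterior` = 0.5, tunable on validation data). Each seed is dilated by
its category's effective erosion depth and refined with a radial spline:
4, 6 or 8 equally spaced rays for S, M and L (star-convex shapes only need
few rays, and small cells support fewer reliable knots). Candidate edge
pixels are weighted by edge probability, down-weighted by a Gaussian
(sigma 3 px) in distance from the grown mask's own boundary, and doubled
inside the overlap channel, where boundaries cross other cells. The knot
on each ray is a local (Gaussian-in-angle) weighted linear regression of
candidate radius on angle evaluated at the ray, plus half a pixel because
edge pixels sit half a pixel inside the continuum boundary; rays with no
candidates fall back to the grown mask's boundary radius. Interpolation is
a periodic cubic spline in angle; any radial function rasterises to a
star-convex mask.

One design choice deserves its own paragraph. On near-perfect semantic
maps, erosion reversal already reconstructs convex cells at IoU ~0.99, and
*no* 4–8-knot radial parameterisation can represent our ellipses better
than about 0.96: redrawing a confirmed boundary through a low-order spline
can only discard information. The spline is therefore fitted always (it is
the exported outline parameterisation), but the instance *mask* adopts the
rasterised spline only when the edge evidence disagrees with the grown
mask by more than 1 px per ray on average. Refinement thus engages exactly
where the predictions are off — which is where a trained CNN needs it —
and never degrades a boundary the evidence already confirms.

A cell near a category boundary can seed in two channels; duplicates are
resolved greedily by score (mean interior probability under the mask),
dropping any instance with IoU above 0.5 against a kept one. True
mother–bud overlaps are far below 0.5, so genuinely overlapping cells
survive.

## The small U-net

The network is a conventional U-net kept deliberately tiny: four
resolution levels, 8 base filters doubling per level, two 3x3
convolutions per encoder block, nearest-neighbour upsampling with two
decoder convolutions per level, and a 1x1 sigmoid head with eight
outputs. Z sections enter as input channels of a single 2-D network.
Forward and backward passes are written directly in R as im2col plus BLAS
matrix products; gradients are verified against numerical differentiation
in the test suite.

Training uses Adam (learning rate 4e-3 with cosine decay to 10%, one
image per step, matching training on single images), binary cross-entropy
with a positive-class weight of 5 (the targets are sparse; an unweighted
loss collapses to all-background within the short schedules used here) and
a per-channel weight of 2 on the bud-neck channel, whose targets are the
sparsest. Inputs are centred about the mid-grey background. Validation
splits hold out whole colonies, never frames of a colony seen in training.

The desk-scale experiment in the test suite trains on 200 five-section
stacks from 20 colonies for 3 epochs and evaluates pixel F1 pooled over
the three interior channels on 4 held-out colonies, reaching about 0.85
against a shuffled-target control near zero. Five-section input matters:
with a single section the off-focus small buds are essentially
undetectable and the S/M interior channels are never learned. The `oracle`
bypass (`oraclePredict`, optionally blurred) decouples every downstream
stage from training quality.

## Tracking

Each segmented instance is summarised by translation- and
rotation-insensitive morphology (area, perimeter, axis lengths,
eccentricity, boundary-radius mean and sd) plus its centroid. Two
gradient-boosted classifiers score pairs across time: classifier A sees
only morphology differences and log-ratios; classifier B additionally
sees centroid distance and mask IoU. Mask IoU is grouped with distance in
B — not with the shared morphology features — because IoU between time
points is itself position-sensitive: a pivoted cell has near-zero IoU with
itself, and giving IoU to A would defeat the pivot-robust path.

Per frame, each active track contributes the mean probability over its
buffered instances from the last three time points, for both classifiers.
A link is admissible when either aggregated probability clears `pMin`
(0.5); among admissible links, an optimal one-to-one assignment (Hungarian
algorithm, cross-checked against brute force in the tests) maximises
PA + 0.5 PB. The additive form implements deferral without veto power: A
decides wherever it separates candidates; B breaks the ties A cannot see
(identically sized sister buds) but cannot override a confident
morphological match after a pivot, and a confident positional match can
rescue a frame where segmentation transiently distorted a cell's shape. An
earlier variant that replaced A's scores by B's when A was ambiguous
split tracks exactly when a pivoted bud had an identical sister; the
additive rule is the package's resolution of that conflict. The pairwise
`trackProbability` helper retains the simple sequential rule (A, deferring
to B below 0.75) for interactive use. Unmatched instances open new tracks
(new buds, cells swept in by the flow); tracks unseen for more than
`lostPatience` = 2 frames are closed.

## Lineage

For every close pair in a frame (mask gap at most 6 px; the smaller cell
is the bud), a third classifier estimates the probability that the pair is
a mother and bud, from the pair's morphology (size ratio, distance, gap)
and bud-neck evidence: the fraction of the frame's bud-neck probability
mass inside a 3 px dilation of the two masks' contact zone, and its mean
there. Training negatives include far pairs so the distance scale is
learned rather than extrapolated. Per-frame probabilities accumulate as
running sums in the `LineageLedger` ("accumulated probability"; a mean
variant is exposed as an option through the ledger columns). A bud is
assigned the candidate mother with the highest accumulated sum among
candidates observed jointly for at least three time points; ties break by
higher mean probability, then lower track id.

## Volumes and growth

The conical method elevates each mask pixel by its Euclidean distance to
the background and integrates the two mirror-symmetric halves:
V = 2 px^3 * sum(heights), converging to (2/3) pi r^3 for a disc. The raw
lattice distance runs to the nearest background pixel *centre*, which
overshoots the mask boundary by up to half a pixel — a bias of ~4% for
bud-sized cells — so the distance map is evaluated on a 2x pixel-replicated
mask and rescaled, bringing discs of radius 20–40 px within ~1% of the
closed form. The calibration factor is configurable (a sphere-equivalent
convention would double the estimate; the default 1.0 keeps the raw
conical value).

Volume series (times in minutes, missing frames flagged and omitted) are
smoothed with a zero-mean GP after centring: Matern-5/2 kernel plus white
noise by default (squared-exponential exposed as an option), with
hyperparameters by marginal-likelihood maximisation from three seeded
restarts, length-scale bounded between one sampling interval and the full
window, and a noise floor of 1e-3 of the volume variance. The growth rate
is the analytically differentiated posterior: its mean from the kernel's
first derivative against the training points and its sd from the
derivative covariance, reported in um^3/h. A cell's total growth rate is
the mother's plus the bud's, with variances added under a documented
independence assumption.

Cytokinesis is estimated as the end of the peak in the bud's growth rate:
the first time after the rate maximum at which the rate falls to
`alpha` = 0.5 of that maximum; a series that never falls below the
threshold returns the last time point flagged. On simulated buds — whose
growth rate drops sharply at division because the daughter grows at 15% of
the bud rate — the detector lands within two time points of the true
division for essentially all events with at least four frames of
post-division observation (events cut off by the end of the movie cannot
be detected by any rate-drop criterion and are excluded from the
benchmark denominator).

The escape fraction is the fraction of mother cells with at least one bud
or daughter whose growth rate has exceeded a threshold (default
15 um^3/h) at or before the query time. It is non-decreasing in time and
non-increasing in the threshold, and is emitted per time point by the
pipeline for consumption by external experiment controllers.

## Evaluation

The metric suite mirrors standard practice for this problem class. Masks
are matched greedily in descending IoU with unmatched predictions scored
zero; average precision integrates the precision–recall points over IoU
thresholds 0.50–0.95 in steps of 0.05 by the non-interpolated trapezoid
rule with a left anchor at zero recall. Track correspondence per frame
requires mask IoU >= 0.5; the track IoU is the number of agreeing time
points over the number of time points where either track has a mask, so
splitting a track into k pieces scores 1/k. The fraction of complete
tracks uses a duration tolerance of 2 frames. MOTA follows the CLEAR
convention: still-valid correspondences are kept frame to frame, an
identity switch is counted when a ground-truth track changes its matched
prediction, and MOTA = 1 - (FN + FP + IDSW) / (total ground-truth
objects). Lineage precision/recall counts a ground-truth pair as a true
positive when the bud's matched predicted track is assigned to the
mother's matched predicted track, with an option to restrict to central
trapped cells. Growth-rate RMSE matches masks per frame by highest
positive IoU ignoring tracking, fits GPs to matched and ground-truth
volume series per ground-truth track, and bootstraps 90% of the
(track, time) samples (1000 repetitions by default at desk scale).

## Numerical choices and problem sizes

Pixel coordinates are 1-based (row, column) throughout, as idiomatic in R.
Seeds are threaded explicitly: the simulator, the U-net (weight init and
shuffling), the boosted classifiers, the GP restarts and the bootstrap are
all reproducible, and equal configurations give identical outputs.
The test suite and the acceptance script run entirely on synthetic data
generated at run time; the scales used — colonies of 1–3 mothers over
10–40 frames, 20-colony segmentation benchmarks, 50 GP recovery series,
one 200-image training run — were chosen as the smallest sizes at which
the properties under test are stable across seeds.

## Known limitations

* The renderer is schematic; nothing is claimed about robustness to real
  bright-field artefacts, and the trained tiny U-net is not expected to
  transfer to real images.
* The radial representation caps boundary detail at 4–8 knots; strongly
  non-elliptical or concave cells (rare in budding yeast) would need more
  rays.
* Lineage assignment assumes the bud is the smaller cell of a pair, which
  holds until cytokinesis but can misorder pairs of similar-size cells.
* The cytokinesis heuristic needs post-division observation; division in
  the last few frames of a movie is flagged, not detected.
* GP variances assume independent mother and bud posteriors when summing.
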