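# budwatch

Label-free analysis of budding yeast in time-lapse microscopy: recovering
individual, **overlapping** cell outlines from bright-field Z-stacks,
tracking them through time, assigning buds to their mothers, and
estimating instantaneous single-cell growth rates.

## The problem and the approach

A growing yeast bud emerges from its mother's surface and, in the 2-D
projection a microscope records, genuinely overlaps its mother and often
its sister. A single per-pixel label image cannot represent two cells on
one pixel, so conventional instance segmentation merges or truncates
exactly the cells — the buds — whose volumes carry the physiological
signal.

`budwatch` recovers overlapping instances from *semantic* maps. A small
multi-target U-net (or an oracle bypass for testing) maps a bright-field
Z-stack to eight per-pixel probability maps: morphologically **eroded
cell interiors** and **cell edges**, each stratified into three size
categories chosen to minimise within-category overlap; all **pairwise
overlaps**; and the **bud necks**. Per category, the eroded interiors are
connected seeds even where cells overlap; instances are recovered by
reversing the erosion and refining each outline against the edge map with
a star-convex radial spline r(theta) on 4–8 rays,

    mask(x) = { x : |x - c| <= r(angle(x - c)) },

so two cells can lay claim to the same pixel.

Tracking is classifier-based: gradient-boosted trees score every
(previous, current) pair of outlines, once from morphology alone (robust
to colonies that pivot under flow) and once with position added; scores
are aggregated over the last three time points and resolved by an optimal
one-to-one assignment. A third classifier combines bud-neck evidence with
pair morphology; its per-frame probabilities accumulate so that each bud
is assigned the mother with the highest accumulated pairing probability
over at least three jointly observed time points.

Cell volume comes from the conical method, V = 2 px^3 * sum of each mask
pixel's distance to background (→ (2/3) pi r^3 for a disc). Volume series
are smoothed by Gaussian-process regression (Matern-5/2 + white noise,
hyperparameters by marginal likelihood), and the **growth rate is the
derivative of the GP posterior**, mean and sd, in um^3/h; a cell's total
rate is mother + bud. On top of this sit a cytokinesis-time heuristic
(the end of the peak in the bud's growth rate) and the escape-fraction
statistic used for real-time experiment control (fraction of mothers with
a bud/daughter growing faster than 15 um^3/h).

A synthetic trapped-colony generator with exhaustive ground truth
(overlapping masks, tracks, lineage, cytokinesis times, true volumes) and
the field's full metric suite (average precision over IoU thresholds,
track IoU, complete-track fraction, MOTA, lineage precision/recall,
growth-rate RMSE with bootstrap) make every stage testable without any
external data.

## Worked example

```r
library(budwatch)

p <- SimParams(nTimepoints = 20L, seed = 42L)
mv <- simulateColony(p)                    # movie + ground truth
dir <- file.path(tempdir(), "colony42")
emitGroundTruth(mv, dir)                   # TIFFs + CSV tables

bundle <- runPipeline(pipelineConfig(dir, mode = "oracle", seed = 1L))
ev <- evaluatePipeline(bundle, mv)
```

This simulates two trapped mothers for 20 frames (5 min apart, five Z
sections, 0.263 um/px), runs segmentation → tracking → lineage → growth
with oracle semantic maps, and scores the result against the ground
truth. The run prints:

```
mean AP 0.989 | complete tracks 1.00 | MOTA 1.000 | lineage P 1.00 R 1.00

  bud_track mother_track accumulated_p joint_frames
1         3            1      18.93748           20
2         4            2      17.95355           19

GrowthEstimate: track 3, 20 points, rate 7.57 to 11.79 um^3/h
  time     rate   rate_sd
1    0 7.565810 1.8583276
2    5 8.484345 1.1632273
3   10 9.187554 0.7965208
4   15 9.555869 0.7267568
```

Every cell was recovered and tracked (mean average precision 0.989 over
IoU thresholds 0.50–0.95; no identity switches), both buds were assigned
to the correct mothers with pairing probability accumulated over ~20
joint frames, and bud track 3's instantaneous growth rate rises from
about 7.6 to 11.8 um^3/h with its GP uncertainty alongside — the kind of
single-cell trajectory the method exists to measure.

A thin command-line interface wraps the same functions
(`inst/scripts/budwatch` with subcommands `simulate`, `run`, `evaluate`),
and `trainUnet()`/`predictSemantic()` replace the oracle with a trained
network where wanted; see the methods vignette
(`vignettes/budwatch-methods.Rmd`) for the model, parameters and design
choices.

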