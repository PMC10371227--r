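Package: budwatch
Title: Segmentation, Tracking, Lineage and Growth of Budding Yeast from
    Bright-Field Time Lapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies individual budding-yeast cells in label-free
    bright-field Z-stacks, including buds that overlap their mothers and
    sisters, and follows them through time. Overlapping instances are
    recovered from size-stratified semantic maps (eroded interiors, edges,
    overlaps and bud necks) by erosion reversal and radial-spline edge
    refinement; cells are tracked with pairwise gradient-boosted classifiers
    aggregated over three time points; buds are assigned to mothers by
    accumulated pairing probabilities informed by the bud-neck map. Cell
    volumes are estimated by the conical method and smoothed with Gaussian
    processes whose derivative posteriors give instantaneous single-cell
    growth rates, a cytokinesis-time heuristic and a real-time escape-fraction
    statistic. Includes a synthetic trapped-colony movie generator with full
    ground truth, a small self-contained multi-target U-net, and the standard
    evaluation suite (average precision over IoU thresholds, track IoU, MOTA,
    lineage precision/recall, growth-rate RMSE with bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
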