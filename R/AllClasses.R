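#' @import methods
#' @importFrom stats median optim qnorm quantile rnorm runif sd spline var setNames
#' @importFrom utils head read.csv tail write.csv
NULL

#' Fixed channel order of the semantic target stack
#'
#' All semantic maps produced or consumed by the package use this eight-channel
#' order: size-stratified eroded interiors (small, medium, large),
#' size-stratified cell edges, the pairwise-overlap channel and the bud-neck
#' channel.
#'
#' @return Character vector of the eight channel names, in order.
#' @export
semanticChannelNames <- function() {
  c("interior_S", "interior_M", "interior_L",
    "edge_S", "edge_M", "edge_L",
    "overlap", "budneck")
}

#' Simulation parameters for synthetic trapped-yeast colonies
#'
#' @slot imageShape integer (H, W) in pixels.
#' @slot pixelSize micrometres per pixel.
#' @slot nZ number of Z sections (1 or 5).
#' @slot zSpacing Z spacing in micrometres.
#' @slot nTimepoints number of time points.
#' @slot samplingInterval minutes between time points.
#' @slot nMothers number of trapped mother cells.
#' @slot motherRadiusRange mother equivalent radius range, pixels.
#' @slot budGrowthRateRange bud growth rate range; um^3/h under the linear
#'   law, 1/h (specific rate) under the exponential law.
#' @slot growthLaw "linear" or "exponential".
#' @slot overlapBias in [0,1]; steers bud placement toward neighbouring cells.
#' @slot pivotProb per-frame probability that a bud pivots about its mother.
#' @slot washoutProb per-frame probability that a non-central (daughter) cell
#'   is washed out of the field.
#' @slot noiseSD additive intensity noise (images are on a [0,1] scale).
#' @slot seed integer seed; identical parameters give identical movies.
#' @export
setClass("SimParams", slots = c(
  imageShape = "integer", pixelSize = "numeric", nZ = "integer",
  zSpacing = "numeric", nTimepoints = "integer", samplingInterval = "numeric",
  nMothers = "integer", motherRadiusRange = "numeric",
  budGrowthRateRange = "numeric", growthLaw = "character",
  overlapBias = "numeric", pivotProb = "numeric", washoutProb = "numeric",
  noiseSD = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be two positive integers")
  if (!object@nZ %in% c(1L, 5L)) msg <- c(msg, "nZ must be 1 or 5")
  for (p in c("overlapBias", "pivotProb", "washoutProb")) {
    v <- slot(object, p)
    if (length(v) != 1L || v < 0 || v > 1)
      msg <- c(msg, paste(p, "must be a probability in [0,1]"))
  }
  if (any(object@motherRadiusRange < 0) ||
      diff(object@motherRadiusRange) < 0)
    msg <- c(msg, "motherRadiusRange must be non-negative and non-decreasing")
  if (any(object@budGrowthRateRange < 0) ||
      diff(object@budGrowthRateRange) < 0)
    msg <- c(msg, "budGrowthRateRange must be non-negative and non-decreasing")
  if (!object@growthLaw %in% c("linear", "exponential"))
    msg <- c(msg, "growthLaw must be 'linear' or 'exponential'")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be non-negative")
  if (object@nTimepoints < 1L) msg <- c(msg, "nTimepoints must be >= 1")
  if (object@samplingInterval <= 0)
    msg <- c(msg, "samplingInterval must be positive")
  if (prod(object@imageShape) == 0)
    msg <- c(msg, "image area must be non-zero")
  if (max(object@motherRadiusRange) * 2 >= min(object@imageShape))
    msg <- c(msg, "mother radius exceeds image")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Defaults emulate ALCATRAS-style trapped colonies imaged every 5 minutes
#' with five bright-field Z sections 0.6 um apart at 0.263 um/px.
#'
#' @param imageShape image height and width in pixels.
#' @param pixelSize um per pixel.
#' @param nZ number of Z sections, 1 or 5.
#' @param zSpacing Z spacing in um.
#' @param nTimepoints number of frames.
#' @param samplingInterval minutes between frames.
#' @param nMothers number of trapped mothers.
#' @param motherRadiusRange equivalent-radius range for mothers, px.
#' @param budGrowthRateRange bud growth rate range (um^3/h linear; 1/h
#'   exponential).
#' @param growthLaw "linear" or "exponential".
#' @param overlapBias bias of bud placement toward neighbours, in [0,1].
#' @param pivotProb per-frame bud pivot probability.
#' @param washoutProb per-frame daughter washout probability.
#' @param noiseSD additive image noise sd.
#' @param seed integer seed.
#' @return A [SimParams-class] object.
#' @export
SimParams <- function(imageShape = c(96L, 96L), pixelSize = 0.263, nZ = 5L,
                      zSpacing = 0.6, nTimepoints = 40L, samplingInterval = 5,
                      nMothers = 2L, motherRadiusRange = c(9, 13),
                      budGrowthRateRange = c(10, 30), growthLaw = "linear",
                      overlapBias = 0.3, pivotProb = 0.05, washoutProb = 0.01,
                      noiseSD = 0.05, seed = 1L) {
  new("SimParams", imageShape = as.integer(imageShape),
      pixelSize = pixelSize, nZ = as.integer(nZ), zSpacing = zSpacing,
      nTimepoints = as.integer(nTimepoints),
      samplingInterval = samplingInterval, nMothers = as.integer(nMothers),
      motherRadiusRange = as.numeric(motherRadiusRange),
      budGrowthRateRange = as.numeric(budGrowthRateRange),
      growthLaw = growthLaw, overlapBias = overlapBias,
      pivotProb = pivotProb, washoutProb = washoutProb, noiseSD = noiseSD,
      seed = as.integer(seed))
}

#' A time point's annotated cell masks
#'
#' Holds one time point's set of possibly overlapping per-cell binary masks,
#' their track labels (unique within the frame) and any mother-bud pairs,
#' given as (bud label, mother label) rows.
#'
#' @slot masks list of logical H x W matrices, one per cell.
#' @slot labels integer track label per mask.
#' @slot motherPairs integer matrix with columns bud, mother (track labels).
#' @slot dim integer (H, W); kept explicitly so empty frames are well formed.
#' @export
setClass("AnnotatedFrame", slots = c(
  masks = "list", labels = "integer", motherPairs = "matrix",
  dim = "integer"))

setValidity("AnnotatedFrame", function(object) {
  msg <- character()
  if (length(object@masks) != length(object@labels))
    msg <- c(msg, "one label per mask required")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "labels must be unique within a frame")
  for (m in object@masks) {
    if (!is.logical(m) || !identical(dim(m), object@dim))
      msg <- c(msg, "masks must be logical matrices of the frame dimension")
    else if (!any(m)) msg <- c(msg, "each mask needs >= 1 foreground pixel")
  }
  if (ncol(object@motherPairs) != 2L)
    msg <- c(msg, "motherPairs must have two columns (bud, mother)")
  if (nrow(object@motherPairs) &&
      !all(object@motherPairs %in% object@labels))
    msg <- c(msg, "motherPairs reference missing labels")
  if (length(msg)) unique(msg) else TRUE
})

#' Construct an annotated frame
#'
#' @param masks list of logical matrices (possibly overlapping).
#' @param labels integer track labels, one per mask.
#' @param motherPairs two-column matrix of (bud label, mother label) rows.
#' @param dim frame dimension (H, W); inferred from the first mask if omitted.
#' @return An [AnnotatedFrame-class] object.
#' @export
AnnotatedFrame <- function(masks = list(), labels = integer(),
                           motherPairs = NULL, dim = NULL) {
  if (is.null(dim)) {
    if (!length(masks)) stop("dim required for an empty frame")
    dim <- base::dim(masks[[1L]])
  }
  if (is.null(motherPairs))
    motherPairs <- matrix(integer(), ncol = 2L,
                          dimnames = list(NULL, c("bud", "mother")))
  storage.mode(motherPairs) <- "integer"
  new("AnnotatedFrame", masks = lapply(masks, function(m) m != 0),
      labels = as.integer(labels), motherPairs = motherPairs,
      dim = as.integer(dim))
}

#' Eight-channel semantic target stack
#'
#' @slot channels numeric H x W x 8 array, third dimension named as in
#'   [semanticChannelNames()]. Values are {0,1} for training targets and
#'   [0,1] probabilities for predictions.
#' @slot binary TRUE for targets, FALSE for predicted probabilities.
#' @export
setClass("SemanticTargets", slots = c(channels = "array", binary = "logical"))

setValidity("SemanticTargets", function(object) {
  ch <- object@channels
  if (length(dim(ch)) != 3L || dim(ch)[3L] != 8L)
    return("channels must be an H x W x 8 array")
  if (!identical(dimnames(ch)[[3L]], semanticChannelNames()))
    return("third dimension must be named by semanticChannelNames()")
  if (min(ch) < 0 || max(ch) > 1)
    return("channel values must lie in [0,1]")
  if (object@binary && !all(ch %in% c(0, 1)))
    return("binary targets must be 0/1")
  TRUE
})

#' Construct a semantic target stack
#' @param channels H x W x 8 array (third-dimension names are set here).
#' @param binary whether the stack holds binary targets.
#' @return A [SemanticTargets-class] object.
#' @export
SemanticTargets <- function(channels, binary = TRUE) {
  dimnames(channels) <- c(dimnames(channels)[1:2] %||% list(NULL, NULL),
                          list(semanticChannelNames()))
  new("SemanticTargets", channels = channels, binary = binary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Size-category specification for target generation
#'
#' @slot boundaries two strictly increasing area thresholds (px^2) splitting
#'   small/medium/large; intervals are half-open: [0,b1), [b1,b2), [b2,Inf).
#' @slot erosionDepth erosion depth in px per category (S, M, L).
#' @slot minSeedArea minimum per-cell area (px^2) kept after erosion.
#' @export
setClass("SizeCategorySpec", slots = c(
  boundaries = "numeric", erosionDepth = "numeric", minSeedArea = "numeric"))

setValidity("SizeCategorySpec", function(object) {
  msg <- character()
  if (length(object@boundaries) != 2L || diff(object@boundaries) <= 0)
    msg <- c(msg, "boundaries must be two strictly increasing thresholds")
  if (length(object@erosionDepth) != 3L || any(object@erosionDepth < 0))
    msg <- c(msg, "erosionDepth must be three non-negative depths")
  if (object@minSeedArea < 1) msg <- c(msg, "minSeedArea must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a size-category specification
#' @param boundaries two increasing area thresholds in px^2.
#' @param erosionDepth per-category erosion depths (S, M, L) in px.
#' @param minSeedArea minimum retained area after erosion, px^2.
#' @return A [SizeCategorySpec-class] object.
#' @export
SizeCategorySpec <- function(boundaries, erosionDepth = c(1, 2, 3),
                             minSeedArea = 5) {
  new("SizeCategorySpec", boundaries = as.numeric(boundaries),
      erosionDepth = as.numeric(erosionDepth),
      minSeedArea = as.numeric(minSeedArea))
}

#' Star-convex radial-spline outline
#'
#' A cell boundary parameterised by knot radii along equally spaced rays from
#' a centre, interpolated periodically in angle. Any radial function gives a
#' star-convex region about the centre.
#'
#' @slot centre (row, col) centre in pixels (1-based).
#' @slot knotAngles ray angles in radians, strictly increasing in [0, 2*pi).
#' @slot knotRadii positive radius (px) at each ray.
#' @export
setClass("RadialSpline", slots = c(
  centre = "numeric", knotAngles = "numeric", knotRadii = "numeric"))

setValidity("RadialSpline", function(object) {
  msg <- character()
  if (length(object@centre) != 2L) msg <- c(msg, "centre must be (row, col)")
  if (length(object@knotAngles) != length(object@knotRadii))
    msg <- c(msg, "one radius per ray")
  if (any(object@knotRadii <= 0)) msg <- c(msg, "radii must be positive")
  if (is.unsorted(object@knotAngles, strictly = TRUE))
    msg <- c(msg, "knotAngles must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' One segmented cell instance
#'
#' @slot spline the refined [RadialSpline-class] outline.
#' @slot mask rasterised logical mask.
#' @slot category size category, "S", "M" or "L".
#' @slot score mean interior probability under the mask, in [0,1].
#' @export
setClass("SegmentedInstance", slots = c(
  spline = "RadialSpline", mask = "matrix", category = "character",
  score = "numeric"))

setValidity("SegmentedInstance", function(object) {
  msg <- character()
  if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
  if (object@score < 0 || object@score > 1)
    msg <- c(msg, "score must be in [0,1]")
  if (!object@category %in% c("S", "M", "L"))
    msg <- c(msg, "category must be S, M or L")
  if (length(msg)) msg else TRUE
})

#' Simulated trapped-colony movie with full ground truth
#'
#' @slot frames list of [AnnotatedFrame-class], one per time point.
#' @slot images list of H x W x nZ arrays (rendered bright-field stacks).
#' @slot trueVolumes data.frame(track, timeIdx, time, volume) in um^3/min.
#' @slot trueCytokinesis data.frame(bud_track, cyto_t) with the frame index of
#'   cytokinesis per bud.
#' @slot lineage data.frame(bud_track, mother_track).
#' @slot params the [SimParams-class] used.
#' @export
setClass("SimulatedMovie", slots = c(
  frames = "list", images = "list", trueVolumes = "data.frame",
  trueCytokinesis = "data.frame", lineage = "data.frame",
  params = "SimParams"))

#' Accumulated mother-bud pairing evidence
#'
#' For each (mother track, bud track) candidate the ledger keeps the running
#' sum of per-frame pairing probabilities and the number of frames on which
#' both tracks were present and a probability was recorded. A bud's mother is
#' the candidate with the highest accumulated sum, subject to a minimum number
#' of joint frames.
#'
#' @slot table data.frame(mother_track, bud_track, psum, count).
#' @export
setClass("LineageLedger", slots = c(table = "data.frame"))

setValidity("LineageLedger", function(object) {
  tb <- object@table
  need <- c("mother_track", "bud_track", "psum", "count")
  if (!all(need %in% names(tb))) return("ledger columns missing")
  if (nrow(tb) && (any(tb$psum < 0) || any(tb$count < 1)))
    return("psum must be >= 0 and count >= 1")
  TRUE
})

#' Construct an empty lineage ledger
#' @return A [LineageLedger-class] with no entries.
#' @export
LineageLedger <- function() {
  new("LineageLedger", table = data.frame(
    mother_track = integer(), bud_track = integer(),
    psum = numeric(), count = integer()))
}

#' Per-track volume time series
#'
#' @slot track track id.
#' @slot times minutes, strictly increasing.
#' @slot volumes um^3; NA where missing.
#' @slot missing logical flags (TRUE where no matching mask existed).
#' @export
setClass("VolumeSeries", slots = c(
  track = "integer", times = "numeric", volumes = "numeric",
  missing = "logical"))

setValidity("VolumeSeries", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@times) != length(object@volumes) ||
      length(object@times) != length(object@missing))
    msg <- c(msg, "times, volumes, missing must align")
  ok <- !object@missing
  if (any(!is.finite(object@volumes[ok])) || any(object@volumes[ok] <= 0))
    msg <- c(msg, "present volumes must be finite and positive")
  if (length(msg)) msg else TRUE
})

#' Construct a volume series
#' @param track track id.
#' @param times time points in minutes.
#' @param volumes volumes in um^3 (NA where missing).
#' @param missing logical missing flags; defaults to `is.na(volumes)`.
#' @return A [VolumeSeries-class] object.
#' @export
VolumeSeries <- function(track, times, volumes, missing = is.na(volumes)) {
  new("VolumeSeries", track = as.integer(track), times = as.numeric(times),
      volumes = as.numeric(volumes), missing = as.logical(missing))
}

#' Gaussian-process smoothed volume and growth rate
#'
#' @slot track track id.
#' @slot times minutes (the observed, non-missing time points).
#' @slot volMean,volSD posterior mean and sd of the smoothed volume, um^3.
#' @slot rateMean,rateSD posterior mean and sd of the time derivative, um^3/h.
#' @slot hyper fitted kernel hyperparameters
#'   (signal variance, length-scale in h, noise variance).
#' @slot kernel kernel name used.
#' @export
setClass("GrowthEstimate", slots = c(
  track = "integer", times = "numeric", volMean = "numeric", volSD = "numeric",
  rateMean = "numeric", rateSD = "numeric", hyper = "numeric",
  kernel = "character"))

setValidity("GrowthEstimate", function(object) {
  if (any(object@volSD < 0) || any(object@rateSD < 0))
    return("posterior sds must be non-negative")
  TRUE
})

#' Configuration of the small multi-target U-net
#'
#' @slot depth number of resolution levels (>= 2).
#' @slot baseFilters filters at the top level; doubled at each level down.
#' @slot inSections number of input Z sections (1 or 5), presented as input
#'   channels of a 2-D network.
#' @slot outChannels always 8.
#' @slot epochs,batchSize,learningRate Adam training settings.
#' @slot channelWeights per-channel loss weights for the binary cross-entropy;
#'   the bud-neck channel defaults to weight 2 because its targets are the
#'   sparsest.
#' @slot posWeight weight of foreground pixels in the loss; the semantic
#'   targets are sparse, and an unweighted loss lets early training collapse
#'   to all-background.
#' @slot seed integer seed for weight init and shuffling.
#' @export
setClass("UNetConfig", slots = c(
  depth = "integer", baseFilters = "integer", inSections = "integer",
  outChannels = "integer", epochs = "integer", batchSize = "integer",
  learningRate = "numeric", channelWeights = "numeric",
  posWeight = "numeric", seed = "integer"))

setValidity("UNetConfig", function(object) {
  msg <- character()
  if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
  if (object@outChannels != 8L) msg <- c(msg, "outChannels must be 8")
  if (!object@inSections %in% c(1L, 5L))
    msg <- c(msg, "inSections must be 1 or 5")
  if (length(object@channelWeights) != 8L ||
      any(object@channelWeights <= 0))
    msg <- c(msg, "channelWeights must be 8 positive weights")
  if (length(msg)) msg else TRUE
})

#' Construct a U-net configuration
#' @param depth resolution levels (default 4).
#' @param baseFilters filters at the top level (default 8).
#' @param inSections input Z sections, 1 or 5.
#' @param epochs training epochs.
#' @param batchSize images per Adam step.
#' @param learningRate Adam step size.
#' @param channelWeights 8 per-channel loss weights.
#' @param posWeight foreground-pixel loss weight.
#' @param seed integer seed.
#' @return A [UNetConfig-class] object.
#' @export
UNetConfig <- function(depth = 4L, baseFilters = 8L, inSections = 1L,
                       epochs = 3L, batchSize = 1L, learningRate = 2e-3,
                       channelWeights = c(1, 1, 1, 1, 1, 1, 1, 2),
                       posWeight = 5, seed = 1L) {
  new("UNetConfig", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters),
      inSections = as.integer(inSections), outChannels = 8L,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = learningRate,
      channelWeights = as.numeric(channelWeights),
      posWeight = posWeight, seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %dx%d px (%.3f um/px), %d Z, %d frames @ %g min, %d mothers\n",
    object@imageShape[1], object@imageShape[2], object@pixelSize, object@nZ,
    object@nTimepoints, object@samplingInterval, object@nMothers))
  cat(sprintf("  growth %s %.3g-%.3g, overlapBias %.2f, pivot %.2f, washout %.2f, seed %d\n",
              object@growthLaw, object@budGrowthRateRange[1],
              object@budGrowthRateRange[2], object@overlapBias,
              object@pivotProb, object@washoutProb, object@seed))
})

setMethod("show", "AnnotatedFrame", function(object) {
  cat(sprintf("AnnotatedFrame: %d cells in %dx%d px, %d mother-bud pair(s)\n",
              length(object@masks), object@dim[1], object@dim[2],
              nrow(object@motherPairs)))
})

setMethod("show", "SemanticTargets", function(object) {
  d <- dim(object@channels)
  cat(sprintf("SemanticTargets: %dx%d, 8 channels (%s)\n", d[1], d[2],
              if (object@binary) "binary targets" else "probabilities"))
})

setMethod("show", "SimulatedMovie", function(object) {
  cat(sprintf(
    "SimulatedMovie: %d frames, %d tracks, %d lineage pair(s)\n",
    length(object@frames), length(unique(object@trueVolumes$track)),
    nrow(object@lineage)))
})

setMethod("show", "SegmentedInstance", function(object) {
  cat(sprintf("SegmentedInstance: category %s, area %d px, score %.3f\n",
              object@category, sum(object@mask), object@score))
})

setMethod("show", "GrowthEstimate", function(object) {
  cat(sprintf(
    "GrowthEstimate: track %d, %d points, rate %.2f to %.2f um^3/h\n",
    object@track, length(object@times), min(object@rateMean),
    max(object@rateMean)))
})

setMethod("show", "LineageLedger", function(object) {
  cat(sprintf("LineageLedger: %d candidate pair(s), %d bud track(s)\n",
              nrow(object@table), length(unique(object@table$bud_track))))
})
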