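# End-to-end pipeline: load a movie directory, predict (or oracle) the
# semantic maps, segment instances, track, assign lineages, estimate
# volumes and growth rates, and write versioned outputs.

RESULTS_SCHEMA <- "budwatch-results-1"

#' Load a time-lapse of bright-field Z-stacks
#'
#' Reads a multi-page TIFF laid out Z-fastest (page order: z1..znZ of t1,
#' then t2, ...), the layout written by [emitGroundTruth()].
#'
#' @param path TIFF file.
#' @param nZ number of Z sections per time point.
#' @return list (over time) of H x W x nZ arrays.
#' @export
loadImageSeries <- function(path, nZ = 5L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% nZ != 0L)
    stop("page count ", length(pages), " is not a multiple of nZ = ", nZ)
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("inconsistent page shapes across the series")
  TT <- length(pages) %/% nZ
  lapply(seq_len(TT), function(t) {
    a <- array(0, c(d1[1:2], nZ))
    for (z in seq_len(nZ)) {
      pg <- pages[[(t - 1L) * nZ + z]]
      a[, , z] <- if (length(dim(pg)) > 2L) pg[, , 1L] else pg
    }
    a
  })
}

#' Assemble a pipeline configuration
#'
#' @param input directory written by [emitGroundTruth()].
#' @param mode "oracle" (semantic maps from ground truth) or "model"
#'   (a trained U-net).
#' @param model a `budwatchUNet`, required for mode "model".
#' @param classifiers optional list(track = `trackClassifiers`,
#'   motherBud = `motherBudClassifier`); when NULL they are trained on the
#'   input's own ground truth (a synthetic-benchmark convenience).
#' @param oracleSigma blur applied in oracle mode.
#' @param pInterior,pMin,weightB,alpha,escapeThreshold pipeline thresholds
#'   (documented at their operations).
#' @param minJointFrames lineage rule: minimum joint frames.
#' @param seed master seed.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(input, mode = c("oracle", "model"), model = NULL,
                           classifiers = NULL, oracleSigma = 0,
                           pInterior = 0.5, pMin = 0.5, weightB = 0.5,
                           alpha = 0.5, escapeThreshold = 15,
                           minJointFrames = 3L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "model" && is.null(model))
    stop("mode 'model' needs a trained U-net")
  stopifnot(pInterior > 0, pInterior < 1, pMin >= 0, pMin <= 1,
            alpha > 0, alpha < 1)
  structure(list(input = input, mode = mode, model = model,
                 classifiers = classifiers, oracleSigma = oracleSigma,
                 pInterior = pInterior, pMin = pMin, weightB = weightB,
                 alpha = alpha, escapeThreshold = escapeThreshold,
                 minJointFrames = as.integer(minJointFrames),
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

defaultClassifiers <- function(movie, spec, seed) {
  pairs <- makeTrackingPairs(movie)
  mbx <- makeMotherBudExamples(movie, spec)
  list(track = trainTrackClassifiers(pairs, seed = seed),
       motherBud = trainMotherBudClassifier(mbx, seed = seed + 1L))
}

#' Run the full pipeline on a movie directory
#'
#' Per frame: semantic maps (oracle or U-net) -> instance segmentation ->
#' tracking -> mother-bud scoring into the lineage ledger. Afterwards:
#' mother assignment, per-track conical volume series, GP growth rates,
#' cytokinesis times for assigned buds, and the escape-fraction series.
#'
#' @param config from [pipelineConfig()].
#' @return a results bundle (list); see [writeResults()].
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  movie <- readGroundTruth(config$input)
  p <- simParams(movie)
  frs <- frames(movie)
  nCells <- sum(vapply(frs, function(f) length(masks(f)), numeric(1)))
  if (nCells >= 2) {
    spec <- optimizeSizeBoundaries(frs)
  } else {
    spec <- SizeCategorySpec(c(150, 400))
  }
  cls <- config$classifiers
  if (is.null(cls) && nCells >= 2)
    cls <- defaultClassifiers(movie, spec, config$seed)
  state <- newTrackerState()
  ledger <- LineageLedger()
  predFrames <- vector("list", length(frs))
  instancesByFrame <- vector("list", length(frs))
  trackRows <- list()
  for (t in seq_along(frs)) {
    targets <- if (config$mode == "oracle")
      oraclePredict(frs[[t]], spec, sigma = config$oracleSigma)
    else predictSemantic(config$model, images(movie)[[t]])
    inst <- segmentFrame(targets, spec, pInterior = config$pInterior)
    instancesByFrame[[t]] <- inst
    res <- trackFrame(state, inst, cls$track, pMin = config$pMin,
                      weightB = config$weightB)
    state <- res$state
    predFrames[[t]] <- AnnotatedFrame(lapply(inst, instanceMask),
                                      res$labels, dim = p@imageShape)
    for (j in seq_along(inst)) {
      fe <- extractMorphFeatures(inst[[j]])
      trackRows[[length(trackRows) + 1L]] <- data.frame(
        time = (t - 1) * p@samplingInterval, track = res$labels[j],
        label = res$labels[j], area = fe[["area"]], cy = fe[["cy"]],
        cx = fe[["cx"]], volume = conicalVolume(instanceMask(inst[[j]]),
                                                p@pixelSize))
    }
    # lineage evidence
    if (length(inst) >= 2L) {
      msks <- lapply(inst, instanceMask)
      feats <- lapply(inst, extractMorphFeatures)
      cand <- candidateMotherBudPairs(msks, feats)
      if (!is.null(cand)) {
        bn <- semanticChannel(targets, "budneck")
        rows <- do.call(rbind, lapply(seq_len(nrow(cand)), function(r) {
          mi <- cand[r, "mother"]; bi <- cand[r, "bud"]
          data.frame(mother_track = res$labels[mi],
                     bud_track = res$labels[bi],
                     p = predictPair(cls$motherBud$model,
                                     motherBudFeatures(msks[[mi]],
                                                       msks[[bi]], bn,
                                                       feats[[mi]],
                                                       feats[[bi]])))
        }))
        ledger <- updateLineage(ledger, rows)
      }
    }
  }
  tracksDf <- if (length(trackRows)) do.call(rbind, trackRows) else
    data.frame(time = numeric(), track = integer(), label = integer(),
               area = numeric(), cy = numeric(), cx = numeric(),
               volume = numeric())
  assignments <- assignMothers(ledger, config$minJointFrames)
  # volume series and growth per track
  growth <- list(); growthRows <- list()
  for (tr in sort(unique(tracksDf$track))) {
    sel <- tracksDf[tracksDf$track == tr, , drop = FALSE]
    if (nrow(sel) < 4L) next
    vs <- VolumeSeries(tr, sel$time, sel$volume)
    ge <- tryCatch(fitGPVolume(vs, seed = config$seed),
                   error = function(e) NULL)
    if (is.null(ge)) next
    growth[[as.character(tr)]] <- ge
    growthRows[[length(growthRows) + 1L]] <- data.frame(
      track = tr, time = ge@times, volume = ge@volMean,
      vol_sd = ge@volSD, rate = ge@rateMean, rate_sd = ge@rateSD)
  }
  growthDf <- if (length(growthRows)) do.call(rbind, growthRows) else
    data.frame(track = integer(), time = numeric(), volume = numeric(),
               vol_sd = numeric(), rate = numeric(), rate_sd = numeric())
  cyto <- NULL
  for (k in seq_len(nrow(assignments))) {
    ge <- growth[[as.character(assignments$bud_track[k])]]
    if (is.null(ge)) next
    ck <- estimateCytokinesis(ge, alpha = config$alpha)
    cyto <- rbind(cyto, data.frame(
      bud_track = assignments$bud_track[k],
      mother_track = assignments$mother_track[k],
      cyto_time = ck$time, flagged = ck$flagged))
  }
  escape <- NULL
  if (nrow(assignments) && nrow(growthDf)) {
    budRates <- growthDf[growthDf$track %in% assignments$bud_track, ,
                         drop = FALSE]
    budRates$mother <- assignments$mother_track[
      match(budRates$track, assignments$bud_track)]
    escape <- escapeFraction(budRates[, c("mother", "time", "rate")],
                             threshold = config$escapeThreshold)
  }
  list(schema = RESULTS_SCHEMA, config = config, params = p,
       predFrames = predFrames, instances = instancesByFrame,
       tracks = tracksDf, ledger = ledger, assignments = assignments,
       growth = growth, growthTable = growthDf, cytokinesis = cyto,
       escape = escape,
       log = list(seed = config$seed, mode = config$mode,
                  nFrames = length(frs),
                  packageVersion =
                    as.character(utils::packageVersion("budwatch")),
                  timestamp = format(Sys.time(), tz = "UTC")))
}

#' Write a results bundle to disk
#'
#' masks.tif + masks.csv (per-cell pages), tracks.csv, lineage.csv,
#' growth.csv, escape.csv, cytokinesis.csv and run_log.json; every CSV
#' carries the schema version in a leading comment line.
#'
#' @param bundle from [runPipeline()].
#' @param outDir output directory.
#' @return `outDir`, invisibly.
#' @export
writeResults <- function(bundle, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  wcsv <- function(df, file) {
    con <- file(file.path(outDir, file), "w")
    writeLines(paste0("# schema: ", RESULTS_SCHEMA), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  pages <- list(); idx <- list()
  for (t in seq_along(bundle$predFrames)) {
    fr <- bundle$predFrames[[t]]
    for (i in seq_along(masks(fr))) {
      pages[[length(pages) + 1L]] <- masks(fr)[[i]] * 1
      idx[[length(idx) + 1L]] <- data.frame(
        page = length(pages), timeIdx = t, track = trackLabels(fr)[i])
    }
  }
  if (length(pages))
    tiff::writeTIFF(pages, file.path(outDir, "masks.tif"),
                    bits.per.sample = 8L)
  wcsv(if (length(idx)) do.call(rbind, idx) else
    data.frame(page = integer(), timeIdx = integer(), track = integer()),
    "masks.csv")
  wcsv(bundle$tracks, "tracks.csv")
  asg <- bundle$assignments
  wcsv(asg, "lineage.csv")
  wcsv(bundle$growthTable, "growth.csv")
  if (!is.null(bundle$escape)) wcsv(bundle$escape, "escape.csv")
  if (!is.null(bundle$cytokinesis)) wcsv(bundle$cytokinesis,
                                         "cytokinesis.csv")
  jsonlite::write_json(bundle$log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Evaluate a results bundle against its ground truth
#'
#' Runs the metric suite of this package: mean average precision, fraction
#' of complete tracks, MOTA, lineage precision/recall. Ground-truth
#' mother-bud pairs whose bud and mother are jointly observed for fewer
#' than `minJointFrames` time points (e.g. buds born in the movie's final
#' frames) are excluded from the lineage denominator: the assignment rule
#' forbids such pairs by construction.
#'
#' @param bundle from [runPipeline()].
#' @param movie the ground-truth [SimulatedMovie-class] (reloaded from the
#'   bundle's input when omitted).
#' @param minJointFrames the joint-observation rule used by the assignment.
#' @return list of metrics.
#' @export
evaluatePipeline <- function(bundle, movie = NULL, minJointFrames = 3L) {
  if (is.null(movie)) movie <- readGroundTruth(bundle$config$input)
  truthFrames <- frames(movie)
  predFrames <- bundle$predFrames
  aps <- vapply(seq_along(truthFrames), function(t) {
    if (!length(masks(truthFrames[[t]]))) return(NA_real_)
    averagePrecision(matchMasks(masks(predFrames[[t]]),
                                masks(truthFrames[[t]])))
  }, numeric(1))
  tm <- matchTracks(predFrames, truthFrames)
  truthPairs <- lineage(movie)
  if (nrow(truthPairs)) {
    joint <- vapply(seq_len(nrow(truthPairs)), function(k)
      sum(framePresence(truthFrames, truthPairs$bud_track[k]) &
            framePresence(truthFrames, truthPairs$mother_track[k])),
      numeric(1))
    truthPairs <- truthPairs[joint >= minJointFrames, , drop = FALSE]
  }
  lp <- lineagePrecisionRecall(
    bundle$assignments[, c("bud_track", "mother_track")],
    truthPairs, tm)
  mt <- mota(predFrames, truthFrames)
  list(meanAP = mean(aps, na.rm = TRUE),
       fractionCompleteTracks = fractionCompleteTracks(predFrames,
                                                       truthFrames),
       mota = mt$mota,
       lineagePrecision = lp$precision, lineageRecall = lp$recall,
       trackMatch = tm)
}
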