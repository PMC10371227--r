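# Synthetic trapped-colony movies with exhaustive ground truth.
#
# Cells are ellipses of bounded eccentricity. Each trapped mother cyclically
# nucleates a bud on its boundary; the bud's 2-D outline tracks its true
# volume under the chosen growth law, overlapping the mother by a per-bud
# overlap fraction (and neighbours, when overlapBias steers placement toward
# them). At cytokinesis the bud becomes an independent daughter track that
# may pivot no longer but can be washed out by the medium flow. All ground
# truth (overlapping masks, track labels, lineage, cytokinesis times, true
# volume trajectories) is recorded.

sphereVolumeToRadiusPx <- function(V, pixelSize) {
  (3 * V / (4 * pi))^(1 / 3) / pixelSize
}

radiusPxToSphereVolume <- function(r, pixelSize) {
  (4 / 3) * pi * (r * pixelSize)^3
}

motherPositions <- function(n, dimHW) {
  if (n == 0L) return(matrix(numeric(), ncol = 2L))
  ctr <- (dimHW + 1) / 2
  if (n == 1L) return(matrix(ctr, ncol = 2L))
  rad <- 0.18 * min(dimHW)
  ang <- 2 * pi * (seq_len(n) - 1) / n + pi / 4
  cbind(ctr[1L] + rad * sin(ang), ctr[2L] + rad * cos(ang))
}

cellEllipse <- function(cell, pixelSize, dimHW) {
  req <- sphereVolumeToRadiusPx(cell$V, pixelSize)
  a <- req * sqrt(cell$q); b <- req / sqrt(cell$q)
  rasteriseEllipse(dimHW, cell$centre, a, b, cell$theta)
}

#' Simulate a trapped budding-yeast colony with ground truth
#'
#' Generates an annotated movie under the conditions set by `params`:
#' elliptical mothers fixed in traps, buds nucleating on their boundaries
#' with controlled mother-bud overlap, growth under a linear or exponential
#' law, stochastic pivoting of attached buds, washout of daughters, and full
#' ground truth. Identical parameters (including the seed) give identical
#' movies. Buds are only produced when the upper bud growth rate is positive,
#' so a zero-rate parameterisation yields static mothers.
#'
#' @param params a [SimParams-class] object.
#' @param render if TRUE (default) also render bright-field Z-stacks.
#' @return A [SimulatedMovie-class] object.
#' @export
simulateColony <- function(params, render = TRUE) {
  validObject(params)
  set.seed(params@seed)
  H <- params@imageShape[1L]; W <- params@imageShape[2L]
  px <- params@pixelSize
  dtH <- params@samplingInterval / 60
  TT <- params@nTimepoints
  pos <- motherPositions(params@nMothers, c(H, W))

  cells <- list()     # keyed by track id (as character)
  nextTrack <- 1L
  newTrack <- function() { id <- nextTrack; nextTrack <<- nextTrack + 1L; id }

  for (i in seq_len(params@nMothers)) {
    req <- runif(1, params@motherRadiusRange[1L], params@motherRadiusRange[2L])
    id <- newTrack()
    cells[[as.character(id)]] <- list(
      track = id, role = "mother", centre = pos[i, ],
      q = runif(1, 1, 1.25), theta = runif(1, 0, pi),
      V = radiusPxToSphereVolume(req, px), g = 0,
      motherTrack = NA_integer_, budAngle = NA_real_,
      overlapFrac = NA_real_, divThresh = NA_real_,
      refractoryUntil = sample(1:3, 1), alive = TRUE)
  }

  allowBuds <- max(params@budGrowthRateRange) > 0
  budV0 <- 4                      # um^3 at nucleation
  framesList <- vector("list", TT)
  imagesList <- vector("list", TT)
  volRows <- list(); pairRows <- list(); cytoRows <- list(); linRows <- list()

  drawBudAngle <- function(mother) {
    others <- Filter(function(c) c$alive && c$track != mother$track, cells)
    if (length(others) && runif(1) < params@overlapBias) {
      tgt <- others[[sample(length(others), 1)]]
      d <- tgt$centre - mother$centre
      atan2(d[1L], d[2L]) + rnorm(1, 0, 0.3)
    } else runif(1, 0, 2 * pi)
  }

  for (t in seq_len(TT)) {
    # pivots: attached buds rotate about their mothers
    for (k in names(cells)) {
      cl <- cells[[k]]
      if (cl$alive && cl$role == "bud" && runif(1) < params@pivotProb)
        cells[[k]]$budAngle <- cl$budAngle +
          sample(c(-1, 1), 1) * runif(1, 0.3, 1.2)
    }
    # washouts: daughters (non-central cells) may leave with the flow
    for (k in names(cells)) {
      cl <- cells[[k]]
      if (cl$alive && cl$role == "daughter" &&
          runif(1) < params@washoutProb)
        cells[[k]]$alive <- FALSE
    }
    # growth
    for (k in names(cells)) {
      cl <- cells[[k]]
      if (!cl$alive || cl$g == 0) next
      cells[[k]]$V <- if (params@growthLaw == "linear")
        cl$V + cl$g * dtH else cl$V * exp(cl$g * dtH)
    }
    # cytokinesis: bud detaches once it reaches its division threshold
    for (k in names(cells)) {
      cl <- cells[[k]]
      if (cl$alive && cl$role == "bud" && cl$V >= cl$divThresh) {
        mother <- cells[[as.character(cl$motherTrack)]]
        req_m <- sphereVolumeToRadiusPx(mother$V, px)
        req_b <- sphereVolumeToRadiusPx(cl$V, px)
        d <- budCentreDistance(req_m, req_b, cl$overlapFrac)
        cells[[k]]$centre <- mother$centre +
          d * c(sin(cl$budAngle), cos(cl$budAngle))
        cells[[k]]$role <- "daughter"
        cells[[k]]$g <- cl$g * 0.15   # slow G1 growth after division
        cytoRows[[length(cytoRows) + 1L]] <-
          data.frame(bud_track = cl$track, cyto_t = t)
        cells[[as.character(cl$motherTrack)]]$refractoryUntil <- t + 2L
      }
    }
    # nucleation: refractory mothers with no attached bud produce one
    if (allowBuds) for (k in names(cells)) {
      cl <- cells[[k]]
      if (!cl$alive || cl$role != "mother" || t < cl$refractoryUntil) next
      attached <- any(vapply(cells, function(c)
        c$alive && c$role == "bud" && identical(c$motherTrack, cl$track),
        logical(1)))
      if (attached) next
      id <- newTrack()
      cells[[as.character(id)]] <- list(
        track = id, role = "bud", centre = cl$centre,  # set when rasterising
        q = runif(1, 1, 1.15), theta = runif(1, 0, pi),
        V = budV0,
        g = runif(1, params@budGrowthRateRange[1L],
                  params@budGrowthRateRange[2L]),
        motherTrack = cl$track, budAngle = drawBudAngle(cl),
        overlapFrac = runif(1, 0.08, 0.40),
        divThresh = runif(1, 0.45, 0.60) * cl$V,
        refractoryUntil = NA, alive = TRUE)
      linRows[[length(linRows) + 1L]] <-
        data.frame(bud_track = id, mother_track = cl$track)
    }
    # rasterise and record
    maskList <- list(); labels <- integer(); prs <- NULL
    for (k in names(cells)) {
      cl <- cells[[k]]
      if (!cl$alive) next
      if (cl$role == "bud") {
        mother <- cells[[as.character(cl$motherTrack)]]
        req_m <- sphereVolumeToRadiusPx(mother$V, px)
        req_b <- sphereVolumeToRadiusPx(cl$V, px)
        d <- budCentreDistance(req_m, req_b, cl$overlapFrac)
        cl$centre <- mother$centre + d * c(sin(cl$budAngle), cos(cl$budAngle))
        cells[[k]]$centre <- cl$centre
        cells[[k]]$theta <- cl$budAngle   # long axis along the radial line
        cl$theta <- cl$budAngle
      }
      m <- cellEllipse(cl, px, c(H, W))
      if (!any(m)) next                   # fully clipped: skip this frame
      maskList[[length(maskList) + 1L]] <- m
      labels <- c(labels, cl$track)
      volRows[[length(volRows) + 1L]] <- data.frame(
        track = cl$track, timeIdx = t,
        time = (t - 1) * params@samplingInterval, volume = cl$V)
      if (cl$role == "bud")
        prs <- rbind(prs, c(cl$track, cl$motherTrack))
    }
    if (!is.null(prs)) colnames(prs) <- c("bud", "mother")
    framesList[[t]] <- AnnotatedFrame(maskList, labels, motherPairs = prs,
                                      dim = c(H, W))
    if (render)
      imagesList[[t]] <- renderBrightfieldStack(framesList[[t]], params,
                                                seed = params@seed + 7919L * t)
  }

  bindRows <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  new("SimulatedMovie",
      frames = framesList, images = imagesList,
      trueVolumes = bindRows(volRows, data.frame(
        track = integer(), timeIdx = integer(), time = numeric(),
        volume = numeric())),
      trueCytokinesis = bindRows(cytoRows, data.frame(
        bud_track = integer(), cyto_t = integer())),
      lineage = bindRows(linRows, data.frame(
        bud_track = integer(), mother_track = integer())),
      params = params)
}

#' Render a schematic bright-field Z-stack for one frame
#'
#' Cells are drawn as bright interiors with a dark rim on a mid-grey
#' background; each cell has a focal plane, and its contribution to a Z
#' section is blurred by a sigma that grows with the distance between that
#' section and the cell's focal plane. Additive Gaussian noise with sd
#' `noiseSD` completes the image. This is a schematic renderer, not an optics
#' simulation.
#'
#' @param frame an [AnnotatedFrame-class].
#' @param params a [SimParams-class] (uses imageShape, nZ, noiseSD).
#' @param seed seed for the noise; equal seeds give identical stacks.
#' @return numeric array H x W x nZ with values in [0, 1].
#' @export
renderBrightfieldStack <- function(frame, params, seed = params@seed) {
  H <- params@imageShape[1L]; W <- params@imageShape[2L]
  nZ <- params@nZ
  bg <- 0.5; interiorLift <- 0.14; rimDrop <- -0.28
  set.seed(seed)
  mk <- masks(frame); lb <- trackLabels(frame)
  # deterministic per-cell focal plane: large cells in the central section,
  # small buds one section off, alternating by label
  midZ <- (nZ + 1L) %/% 2L
  focal <- if (length(mk)) vapply(seq_along(mk), function(i) {
    if (nZ == 1L || sum(mk[[i]]) > 250) midZ
    else midZ + (lb[i] %% 3L) - 1L
  }, numeric(1)) else numeric()
  planes <- sort(unique(focal))
  deltas <- list()
  for (fp in planes) {
    d <- matrix(0, H, W)
    idx <- which(focal == fp)
    for (i in idx) d[mk[[i]]] <- interiorLift
    for (i in idx) {
      rim <- mk[[i]] & !erodeDisc(mk[[i]], 1.4)
      d[rim] <- rimDrop
    }
    deltas[[as.character(fp)]] <- d
  }
  out <- array(0, dim = c(H, W, nZ))
  for (z in seq_len(nZ)) {
    canvas <- matrix(bg, H, W)
    for (fp in planes) {
      sig <- 0.5 + 0.8 * abs(z - fp)
      canvas <- canvas +
        asMaskMatrix(EBImage::gblur(deltas[[as.character(fp)]], sigma = sig))
    }
    if (params@noiseSD > 0)
      canvas <- canvas + matrix(rnorm(H * W, 0, params@noiseSD), H, W)
    out[, , z] <- pmin(pmax(canvas, 0), 1)
  }
  out
}

#' Write a simulated movie (images, masks, tables) to disk
#'
#' Layout: `images.tif` (multi-page, Z fastest then time), `masks.tif`
#' (one page per cell per time point, an overlap-safe layout) with the page
#' index in `masks.csv` (page, timeIdx, track); `tracks.csv`
#' (time, track, label); `pairs.csv` (timeIdx, bud, mother);
#' `lineage.csv` (bud_track, mother_track, cytokinesis_t); `volumes.csv`;
#' `sim_params.json`.
#'
#' @param movie a [SimulatedMovie-class].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @seealso [readGroundTruth()] for the lossless reload.
#' @export
emitGroundTruth <- function(movie, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  p <- simParams(movie)
  imgs <- images(movie)
  if (length(imgs) && !is.null(imgs[[1L]])) {
    pages <- list()
    for (t in seq_along(imgs)) for (z in seq_len(p@nZ))
      pages[[length(pages) + 1L]] <- imgs[[t]][, , z]
    tiff::writeTIFF(pages, file.path(outDir, "images.tif"),
                    bits.per.sample = 32L)
  }
  maskPages <- list(); maskIdx <- list()
  trackRows <- list(); pairRowsL <- list()
  for (t in seq_along(frames(movie))) {
    fr <- frames(movie)[[t]]
    lb <- trackLabels(fr)
    for (i in seq_along(masks(fr))) {
      maskPages[[length(maskPages) + 1L]] <- masks(fr)[[i]] * 1
      maskIdx[[length(maskIdx) + 1L]] <- data.frame(
        page = length(maskPages), timeIdx = t, track = lb[i])
      trackRows[[length(trackRows) + 1L]] <- data.frame(
        time = (t - 1) * p@samplingInterval, track = lb[i], label = lb[i])
    }
    mp <- motherPairs(fr)
    if (nrow(mp))
      pairRowsL[[length(pairRowsL) + 1L]] <- data.frame(
        timeIdx = t, bud = mp[, 1L], mother = mp[, 2L])
  }
  if (length(maskPages))
    tiff::writeTIFF(maskPages, file.path(outDir, "masks.tif"),
                    bits.per.sample = 8L)
  bindRows <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  write.csv(bindRows(maskIdx, data.frame(page = integer(), timeIdx = integer(),
                                         track = integer())),
            file.path(outDir, "masks.csv"), row.names = FALSE)
  write.csv(bindRows(trackRows, data.frame(time = numeric(), track = integer(),
                                           label = integer())),
            file.path(outDir, "tracks.csv"), row.names = FALSE)
  write.csv(bindRows(pairRowsL, data.frame(timeIdx = integer(),
                                           bud = integer(),
                                           mother = integer())),
            file.path(outDir, "pairs.csv"), row.names = FALSE)
  lin <- lineage(movie)
  cyt <- trueCytokinesis(movie)
  lin$cytokinesis_t <- cyt$cyto_t[match(lin$bud_track, cyt$bud_track)]
  write.csv(lin, file.path(outDir, "lineage.csv"), row.names = FALSE)
  write.csv(trueVolumes(movie), file.path(outDir, "volumes.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(
    imageShape = p@imageShape, pixelSize = p@pixelSize, nZ = p@nZ,
    zSpacing = p@zSpacing, nTimepoints = p@nTimepoints,
    samplingInterval = p@samplingInterval, nMothers = p@nMothers,
    motherRadiusRange = p@motherRadiusRange,
    budGrowthRateRange = p@budGrowthRateRange, growthLaw = p@growthLaw,
    overlapBias = p@overlapBias, pivotProb = p@pivotProb,
    washoutProb = p@washoutProb, noiseSD = p@noiseSD, seed = p@seed),
    file.path(outDir, "sim_params.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Reload a movie written by [emitGroundTruth()]
#'
#' @param dir directory written by [emitGroundTruth()].
#' @return A [SimulatedMovie-class]; masks, labels, pairs, lineage and
#'   volumes round-trip losslessly.
#' @export
readGroundTruth <- function(dir) {
  pj <- jsonlite::read_json(file.path(dir, "sim_params.json"),
                            simplifyVector = TRUE)
  p <- SimParams(imageShape = pj$imageShape, pixelSize = pj$pixelSize,
                 nZ = pj$nZ, zSpacing = pj$zSpacing,
                 nTimepoints = pj$nTimepoints,
                 samplingInterval = pj$samplingInterval,
                 nMothers = pj$nMothers,
                 motherRadiusRange = pj$motherRadiusRange,
                 budGrowthRateRange = pj$budGrowthRateRange,
                 growthLaw = pj$growthLaw, overlapBias = pj$overlapBias,
                 pivotProb = pj$pivotProb, washoutProb = pj$washoutProb,
                 noiseSD = pj$noiseSD, seed = pj$seed)
  TT <- p@nTimepoints
  imgs <- vector("list", TT)
  imgPath <- file.path(dir, "images.tif")
  if (file.exists(imgPath)) {
    pages <- tiff::readTIFF(imgPath, all = TRUE)
    for (t in seq_len(TT)) {
      a <- array(0, dim = c(p@imageShape, p@nZ))
      for (z in seq_len(p@nZ)) a[, , z] <- pages[[(t - 1L) * p@nZ + z]]
      imgs[[t]] <- a
    }
  }
  maskIdx <- read.csv(file.path(dir, "masks.csv"))
  maskPages <- if (nrow(maskIdx))
    tiff::readTIFF(file.path(dir, "masks.tif"), all = TRUE) else list()
  pairs <- read.csv(file.path(dir, "pairs.csv"))
  framesList <- vector("list", TT)
  for (t in seq_len(TT)) {
    sel <- maskIdx$timeIdx == t
    mk <- lapply(maskIdx$page[sel], function(pg) maskPages[[pg]] > 0.5)
    pr <- pairs[pairs$timeIdx == t, , drop = FALSE]
    prm <- if (nrow(pr)) cbind(bud = pr$bud, mother = pr$mother) else NULL
    framesList[[t]] <- AnnotatedFrame(mk, maskIdx$track[sel],
                                      motherPairs = prm, dim = p@imageShape)
  }
  lin <- read.csv(file.path(dir, "lineage.csv"))
  cyt <- lin[!is.na(lin$cytokinesis_t), c("bud_track", "cytokinesis_t")]
  names(cyt) <- c("bud_track", "cyto_t")
  rownames(cyt) <- NULL
  new("SimulatedMovie", frames = framesList, images = imgs,
      trueVolumes = read.csv(file.path(dir, "volumes.csv")),
      trueCytokinesis = cyt,
      lineage = lin[, c("bud_track", "mother_track")], params = p)
}
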