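# Evaluation metrics: mask IoU matching, average precision over IoU
# thresholds, track IoU, fraction of complete tracks, MOTA (CLEAR
# convention) and lineage precision/recall. Pred and truth are both given
# as AnnotatedFrame objects (instances carry their track labels), so the
# same code evaluates the pipeline against simulator ground truth.

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of the same dimension.
#' @return IoU in [0,1]; it is an error for both masks to be empty.
#' @export
maskIoU <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) stop("IoU undefined: both masks empty")
  sum(a & b) / u
}

iouMatrix <- function(preds, truths) {
  out <- matrix(0, length(preds), length(truths))
  for (i in seq_along(preds)) for (j in seq_along(truths)) {
    inter <- sum(preds[[i]] & truths[[j]])
    if (inter > 0)
      out[i, j] <- inter / sum(preds[[i]] | truths[[j]])
  }
  out
}

#' Greedy one-to-one matching of predicted and ground-truth masks
#'
#' Pairs are taken in descending IoU order; unmatched predictions keep an
#' IoU of zero.
#'
#' @param preds,truths lists of logical masks (same image dimensions).
#' @param minIoU smallest IoU allowed to form a pair (default: any positive
#'   overlap).
#' @return list with `pairs` (data.frame pred, truth, iou), `unmatchedPred`
#'   and `unmatchedTruth` (integer indices).
#' @export
matchMasks <- function(preds, truths, minIoU = 0) {
  M <- iouMatrix(preds, truths)
  pairs <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  if (length(preds) && length(truths)) {
    repeat {
      best <- which.max(M)
      if (!length(best) || M[best] <= 0 || M[best] < minIoU) break
      j <- (best - 1L) %/% nrow(M) + 1L
      i <- best - (j - 1L) * nrow(M)
      pairs <- rbind(pairs, data.frame(pred = i, truth = j, iou = M[i, j]))
      M[i, ] <- -1; M[, j] <- -1
    }
  }
  list(pairs = pairs,
       unmatchedPred = setdiff(seq_along(preds), pairs$pred),
       unmatchedTruth = setdiff(seq_along(truths), pairs$truth))
}

#' Average precision over a sweep of IoU thresholds
#'
#' At each threshold, matched pairs with IoU at or above the threshold are
#' true positives; remaining predictions are false positives and remaining
#' ground-truth cells false negatives. The (recall, precision) points are
#' integrated by the non-interpolated trapezoid rule with a left anchor at
#' zero recall.
#'
#' @param match result of [matchMasks()].
#' @param nPred,nTruth numbers of predicted and ground-truth masks;
#'   inferred from `match` when omitted.
#' @param thresholds IoU threshold grid.
#' @return AP in [0,1].
#' @export
averagePrecision <- function(match, nPred = NULL, nTruth = NULL,
                             thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (is.null(nPred))
    nPred <- nrow(match$pairs) + length(match$unmatchedPred)
  if (is.null(nTruth))
    nTruth <- nrow(match$pairs) + length(match$unmatchedTruth)
  if (nTruth == 0) stop("no ground-truth masks")
  if (nPred == 0) return(0)
  pts <- t(vapply(thresholds, function(t) {
    tp <- sum(match$pairs$iou >= t)
    c(recall = tp / nTruth, precision = if (nPred) tp / nPred else 0)
  }, numeric(2)))
  pts <- pts[order(pts[, "recall"]), , drop = FALSE]
  r <- c(0, pts[, "recall"]); p <- c(pts[1L, "precision"], pts[, "precision"])
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

framePresence <- function(frames, track) {
  vapply(frames, function(fr) track %in% trackLabels(fr), logical(1))
}

#' Per-frame label maps between predicted and ground-truth cells
#'
#' At each time point, predicted and ground-truth masks are paired in
#' descending mask-IoU order, keeping only pairs with IoU above
#' `iouThreshold`.
#'
#' @param predFrames,truthFrames lists of [AnnotatedFrame-class].
#' @param iouThreshold minimum mask IoU for a valid correspondence.
#' @return list (one per frame) of data.frames (pred, truth) of track labels.
#' @export
frameLabelMaps <- function(predFrames, truthFrames, iouThreshold = 0.5) {
  lapply(seq_along(truthFrames), function(t) {
    pf <- predFrames[[t]]; tf <- truthFrames[[t]]
    mm <- matchMasks(masks(pf), masks(tf), minIoU = iouThreshold)
    if (!nrow(mm$pairs))
      return(data.frame(pred = integer(), truth = integer()))
    data.frame(pred = trackLabels(pf)[mm$pairs$pred],
               truth = trackLabels(tf)[mm$pairs$truth])
  })
}

#' Track IoU between one predicted and one ground-truth track
#'
#' The number of time points where the predicted label maps to the
#' ground-truth label, divided by the number of time points at which either
#' track has a mask. Splitting a track is thereby penalised.
#'
#' @param predTrack,truthTrack track labels.
#' @param labelMaps from [frameLabelMaps()].
#' @param predFrames,truthFrames the frame lists.
#' @return track IoU in [0,1].
#' @export
trackIoU <- function(predTrack, truthTrack, labelMaps, predFrames,
                     truthFrames) {
  agree <- sum(vapply(labelMaps, function(m)
    any(m$pred == predTrack & m$truth == truthTrack), logical(1)))
  either <- sum(framePresence(predFrames, predTrack) |
                  framePresence(truthFrames, truthTrack))
  if (either == 0) return(0)
  agree / either
}

#' Match predicted to ground-truth tracks by descending track IoU
#'
#' @param predFrames,truthFrames lists of [AnnotatedFrame-class].
#' @param iouThreshold mask-IoU threshold defining per-frame correspondence.
#' @return list with `table` (data.frame truth_track, pred_track — NA when
#'   unmatched — and track_iou), `unmatchedPred` (pred tracks left
#'   unassigned, which score 0) and `labelMaps`.
#' @export
matchTracks <- function(predFrames, truthFrames, iouThreshold = 0.5) {
  maps <- frameLabelMaps(predFrames, truthFrames, iouThreshold)
  predTracks <- sort(unique(unlist(lapply(predFrames, trackLabels))))
  truthTracks <- sort(unique(unlist(lapply(truthFrames, trackLabels))))
  M <- matrix(0, length(predTracks), length(truthTracks),
              dimnames = list(predTracks, truthTracks))
  for (i in seq_along(predTracks)) for (j in seq_along(truthTracks))
    M[i, j] <- trackIoU(predTracks[i], truthTracks[j], maps, predFrames,
                        truthFrames)
  tab <- data.frame(truth_track = truthTracks,
                    pred_track = NA_integer_, track_iou = 0)
  if (length(predTracks) && length(truthTracks)) {
    W <- M
    repeat {
      best <- which.max(W)
      if (!length(best) || W[best] <= 0) break
      j <- (best - 1L) %/% nrow(W) + 1L
      i <- best - (j - 1L) * nrow(W)
      tab$pred_track[j] <- predTracks[i]
      tab$track_iou[j] <- W[i, j]
      W[i, ] <- -1; W[, j] <- -1
    }
  }
  list(table = tab,
       unmatchedPred = setdiff(predTracks, tab$pred_track),
       labelMaps = maps)
}

trackDuration <- function(frames, track) sum(framePresence(frames, track))

#' Fraction of ground-truth tracks recovered (near) completely
#'
#' A ground-truth track counts as complete when its matched predicted track
#' exists and the two durations (numbers of frames with a mask) differ by at
#' most `missingTolerance` frames.
#'
#' @param predFrames,truthFrames lists of [AnnotatedFrame-class].
#' @param missingTolerance allowed duration difference in frames.
#' @param iouThreshold mask-IoU threshold for correspondences.
#' @return fraction in [0,1].
#' @export
fractionCompleteTracks <- function(predFrames, truthFrames,
                                   missingTolerance = 2,
                                   iouThreshold = 0.5) {
  tm <- matchTracks(predFrames, truthFrames, iouThreshold)
  tab <- tm$table
  if (!nrow(tab)) return(NA_real_)
  ok <- vapply(seq_len(nrow(tab)), function(k) {
    if (is.na(tab$pred_track[k])) return(FALSE)
    dp <- trackDuration(predFrames, tab$pred_track[k])
    dt <- trackDuration(truthFrames, tab$truth_track[k])
    abs(dp - dt) <= missingTolerance
  }, logical(1))
  mean(ok)
}

#' Multiple Object Tracking Accuracy
#'
#' CLEAR convention: correspondences at each frame are valid if mask IoU is
#' at least `iouThreshold`; existing (truth, pred) correspondences are kept
#' while still valid, remaining cells are matched in descending IoU order.
#' An identity switch is counted when a ground-truth track's matched
#' predicted track differs from the one it last held. MOTA = 1 - (FN + FP +
#' IDSW) / total ground-truth objects.
#'
#' @param predFrames,truthFrames lists of [AnnotatedFrame-class].
#' @param iouThreshold validity threshold for correspondences.
#' @return list(mota, fn, fp, idsw, nTruth).
#' @export
mota <- function(predFrames, truthFrames, iouThreshold = 0.5) {
  nTruth <- sum(vapply(truthFrames, function(f) length(masks(f)),
                       numeric(1)))
  if (nTruth == 0) stop("no ground-truth objects")
  fn <- 0L; fp <- 0L; idsw <- 0L
  lastMatch <- list()    # truth track -> pred track it last corresponded to
  corr <- list()         # current truth -> pred correspondence
  for (t in seq_along(truthFrames)) {
    pf <- predFrames[[t]]; tf <- truthFrames[[t]]
    pmk <- masks(pf); plb <- trackLabels(pf)
    tmk <- masks(tf); tlb <- trackLabels(tf)
    M <- iouMatrix(pmk, tmk)
    usedP <- rep(FALSE, length(pmk)); usedT <- rep(FALSE, length(tmk))
    newCorr <- list()
    # keep still-valid previous correspondences first
    for (tt in names(corr)) {
      j <- match(as.integer(tt), tlb); i <- match(corr[[tt]], plb)
      if (!is.na(i) && !is.na(j) && M[i, j] >= iouThreshold) {
        newCorr[[tt]] <- corr[[tt]]; usedP[i] <- TRUE; usedT[j] <- TRUE
      }
    }
    if (length(pmk) && length(tmk)) {
      W <- M
      W[usedP, ] <- -1; W[, usedT] <- -1
      repeat {
        best <- which.max(W)
        if (!length(best) || W[best] < iouThreshold) break
        j <- (best - 1L) %/% nrow(W) + 1L
        i <- best - (j - 1L) * nrow(W)
        tt <- as.character(tlb[j])
        newCorr[[tt]] <- plb[i]
        if (!is.null(lastMatch[[tt]]) && lastMatch[[tt]] != plb[i])
          idsw <- idsw + 1L
        W[i, ] <- -1; W[, j] <- -1
      }
    }
    matchedT <- as.integer(names(newCorr))
    fn <- fn + sum(!tlb %in% matchedT)
    fp <- fp + sum(!plb %in% unlist(newCorr))
    for (tt in names(newCorr)) lastMatch[[tt]] <- newCorr[[tt]]
    corr <- newCorr
  }
  list(mota = 1 - (fn + fp + idsw) / nTruth, fn = fn, fp = fp, idsw = idsw,
       nTruth = nTruth)
}

#' Lineage assignment precision and recall
#'
#' A ground-truth bud-to-mother pair is a true positive when the bud track
#' has a matched predicted track and that predicted track's predicted mother
#' matches the ground-truth mother's predicted track. Unmatched or
#' wrongly-assigned ground-truth pairs are false negatives; predicted pairs
#' not counted as true positives are false positives.
#'
#' @param predPairs data.frame(bud_track, mother_track) in predicted ids.
#' @param truthPairs data.frame(bud_track, mother_track) in ground-truth ids.
#' @param trackMatch result of [matchTracks()] (pred vs truth frames).
#' @param trackIoUThreshold minimum track IoU for a track match to count.
#' @param centralTracks optional ground-truth mother tracks to restrict to
#'   (the central trapped cells).
#' @return list(precision, recall, tp, fp, fn).
#' @export
lineagePrecisionRecall <- function(predPairs, truthPairs, trackMatch,
                                   trackIoUThreshold = 0,
                                   centralTracks = NULL) {
  tab <- trackMatch$table
  tab <- tab[tab$track_iou > trackIoUThreshold & !is.na(tab$pred_track), ,
             drop = FALSE]
  toPred <- setNames(tab$pred_track, tab$truth_track)
  if (!is.null(centralTracks))
    truthPairs <- truthPairs[truthPairs$mother_track %in% centralTracks, ,
                             drop = FALSE]
  tp <- 0L
  tpPred <- data.frame(bud_track = integer(), mother_track = integer())
  for (k in seq_len(nrow(truthPairs))) {
    pb <- toPred[as.character(truthPairs$bud_track[k])]
    pm <- toPred[as.character(truthPairs$mother_track[k])]
    if (is.na(pb) || is.na(pm)) next
    hit <- predPairs$bud_track == pb & predPairs$mother_track == pm
    if (any(hit)) {
      tp <- tp + 1L
      tpPred <- rbind(tpPred, data.frame(bud_track = pb, mother_track = pm))
    }
  }
  fn <- nrow(truthPairs) - tp
  isTP <- vapply(seq_len(nrow(predPairs)), function(k)
    any(tpPred$bud_track == predPairs$bud_track[k] &
          tpPred$mother_track == predPairs$mother_track[k]), logical(1))
  fp <- if (nrow(predPairs)) sum(!isTP) else 0L
  list(precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Growth-rate RMSE of predicted against ground-truth segmentations
#'
#' Ignores tracking: at each frame every ground-truth mask is matched to the
#' predicted mask of highest positive IoU (one-to-one, descending). Per
#' ground-truth track, conical volumes of the matched predicted masks
#' (missing frames omitted) and of the ground-truth masks are each smoothed
#' with a Gaussian process; the RMSE is taken over all (track, time) growth
#' rate samples where both are defined, with a seeded bootstrap over 90% of
#' the samples.
#'
#' @param predFrames,truthFrames lists of [AnnotatedFrame-class].
#' @param pixelSize um per pixel.
#' @param samplingInterval minutes between frames.
#' @param nBoot bootstrap repetitions (resampling 90% of the samples).
#' @param seed bootstrap seed.
#' @return list(rmse, bootstrap (numeric vector), n, perTrack).
#' @export
growthRMSE <- function(predFrames, truthFrames, pixelSize,
                       samplingInterval = 5, nBoot = 1000, seed = 1L) {
  truthTracks <- sort(unique(unlist(lapply(truthFrames, trackLabels))))
  diffs <- numeric(0); perTrack <- list()
  for (tr in truthTracks) {
    tTimes <- numeric(0); tVol <- numeric(0); pVol <- numeric(0)
    for (t in seq_along(truthFrames)) {
      tf <- truthFrames[[t]]
      j <- match(tr, trackLabels(tf))
      if (is.na(j)) next
      pf <- predFrames[[t]]
      mm <- matchMasks(masks(pf), masks(tf), minIoU = 0)
      hit <- mm$pairs[mm$pairs$truth == j, , drop = FALSE]
      tTimes <- c(tTimes, (t - 1) * samplingInterval)
      tVol <- c(tVol, conicalVolume(masks(tf)[[j]], pixelSize))
      pVol <- c(pVol, if (nrow(hit))
        conicalVolume(masks(pf)[[hit$pred[1L]]], pixelSize) else NA_real_)
    }
    ok <- !is.na(pVol)
    if (length(tTimes) < 4L || sum(ok) < 4L) next
    gt <- fitGPVolume(VolumeSeries(tr, tTimes, tVol))
    gp <- fitGPVolume(VolumeSeries(tr, tTimes[ok], pVol[ok]))
    shared <- intersect(gt@times, gp@times)
    d <- gp@rateMean[match(shared, gp@times)] -
      gt@rateMean[match(shared, gt@times)]
    diffs <- c(diffs, d)
    perTrack[[as.character(tr)]] <- sqrt(mean(d^2))
  }
  if (!length(diffs)) stop("no matched growth-rate samples")
  rmse <- sqrt(mean(diffs^2))
  set.seed(seed)
  k <- max(1L, round(0.9 * length(diffs)))
  boot <- vapply(seq_len(nBoot), function(i)
    sqrt(mean(sample(diffs, k, replace = TRUE)^2)), numeric(1))
  list(rmse = rmse, bootstrap = boot, n = length(diffs),
       perTrack = unlist(perTrack))
}
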