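# Mother-bud assignment: a gradient-boosted classifier scores every close
# pair of cells in a frame using morphology plus bud-neck evidence from the
# semantic maps; per-frame probabilities accumulate in a LineageLedger and
# each bud is assigned the mother with the highest accumulated probability,
# provided the two were observed jointly for at least three time points.

contactZone <- function(maskA, maskB, reach = 2) {
  dilateDisc(maskA, reach) & dilateDisc(maskB, reach)
}

motherBudFeatures <- function(maskM, maskB, budneck = NULL, fM = NULL,
                              fB = NULL) {
  fM <- fM %||% extractMorphFeatures(maskM)
  fB <- fB %||% extractMorphFeatures(maskB)
  dist <- sqrt((fM[["cy"]] - fB[["cy"]])^2 + (fM[["cx"]] - fB[["cx"]])^2)
  gap <- dist - fM[["radMean"]] - fB[["radMean"]]
  sizeRatio <- fB[["area"]] / fM[["area"]]
  neckFrac <- 0; neckMean <- 0
  if (!is.null(budneck) && sum(budneck) > 1e-9) {
    zone <- dilateDisc(contactZone(maskM, maskB), 3)
    if (any(zone)) {
      neckFrac <- sum(budneck[zone]) / sum(budneck)
      neckMean <- mean(budneck[zone])
    }
  }
  c(sizeRatio = sizeRatio, budArea = fB[["area"]],
    motherArea = fM[["area"]], dist = dist, gap = gap,
    normDist = dist / (fM[["radMean"]] + fB[["radMean"]] + 0.1),
    neckFrac = neckFrac, neckMean = neckMean,
    d_ecc = abs(fM[["ecc"]] - fB[["ecc"]]))
}

# Candidate (mother, bud) index pairs in a frame: the bud is the smaller
# cell, and the two must come within `maxGap` px of each other.
candidateMotherBudPairs <- function(msks, feats, maxGap = 6) {
  out <- NULL
  n <- length(msks)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bi <- if (feats[[i]][["area"]] <= feats[[j]][["area"]]) i else j
    mi <- if (bi == i) j else i
    dist <- sqrt((feats[[mi]][["cy"]] - feats[[bi]][["cy"]])^2 +
                   (feats[[mi]][["cx"]] - feats[[bi]][["cx"]])^2)
    if (dist - feats[[mi]][["radMean"]] - feats[[bi]][["radMean"]] > maxGap)
      next
    out <- rbind(out, c(mother = mi, bud = bi))
  }
  out
}

#' Build labelled mother-bud pair examples from a ground-truth movie
#'
#' Positives are the attached (bud, mother) pairs recorded in each frame;
#' negatives are all other pairs, near and far, so the classifier learns
#' both the neck evidence and the distance scale. Bud-neck evidence comes
#' from the oracle target stack of each frame.
#'
#' @param movie a [SimulatedMovie-class].
#' @param spec a [SizeCategorySpec-class] for the oracle maps.
#' @param stride use every `stride`-th frame.
#' @return list(X, y).
#' @export
makeMotherBudExamples <- function(movie, spec, stride = 2L) {
  X <- NULL; y <- integer()
  for (t in seq(1L, length(frames(movie)), by = stride)) {
    fr <- frames(movie)[[t]]
    msks <- masks(fr); lb <- trackLabels(fr)
    if (length(msks) < 2L) next
    bn <- semanticChannel(oraclePredict(fr, spec), "budneck")
    feats <- lapply(msks, extractMorphFeatures)
    cand <- candidateMotherBudPairs(msks, feats, maxGap = Inf)
    if (is.null(cand)) next
    mp <- motherPairs(fr)
    for (r in seq_len(nrow(cand))) {
      mi <- cand[r, "mother"]; bi <- cand[r, "bud"]
      X <- rbind(X, motherBudFeatures(msks[[mi]], msks[[bi]], bn,
                                      feats[[mi]], feats[[bi]]))
      y <- c(y, as.integer(nrow(mp) > 0 &&
                             any(mp[, 1L] == lb[bi] & mp[, 2L] == lb[mi])))
    }
  }
  list(X = X, y = y)
}

#' Train the mother-bud pairing classifier
#' @param examples output of [makeMotherBudExamples()] (fields of several
#'   movies may be row-bound).
#' @param seed boosting seed.
#' @param nrounds boosting rounds; kept moderate so probabilities stay
#'   calibrated on the small synthetic example sets.
#' @return object of class `motherBudClassifier`.
#' @export
trainMotherBudClassifier <- function(examples, seed = 1L, nrounds = 40L) {
  if (length(unique(examples$y)) < 2L)
    stop("need both paired and unpaired examples")
  structure(list(model = fitPairClassifier(examples$X, examples$y, seed,
                                           nrounds = nrounds),
                 featNames = colnames(examples$X)),
            class = "motherBudClassifier")
}

#' Probability that two cells are a mother and her bud
#'
#' Features combine the pair's morphology (size ratio, distance, gap) with
#' bud-neck evidence: the fraction of the frame's bud-neck probability mass
#' that falls within a 3 px dilation of the two masks' contact zone. With an
#' all-zero bud-neck channel the morphology terms alone drive the estimate.
#'
#' @param mother,bud [SegmentedInstance-class] objects or masks (the
#'   smaller cell is treated as the bud regardless of argument order).
#' @param budneck the bud-neck probability channel (matrix), or NULL.
#' @param classifier a `motherBudClassifier`.
#' @return probability in [0,1].
#' @export
motherBudProbability <- function(mother, bud, budneck, classifier) {
  mm <- instMask(mother); mb <- instMask(bud)
  if (sum(mb) > sum(mm)) { tmp <- mm; mm <- mb; mb <- tmp }
  predictPair(classifier$model, motherBudFeatures(mm, mb, budneck))
}

#' Accumulate one frame's pairing probabilities into the ledger
#'
#' @param ledger a [LineageLedger-class].
#' @param framePairs data.frame(mother_track, bud_track, p).
#' @return the updated ledger.
#' @export
updateLineage <- function(ledger, framePairs) {
  if (is.null(framePairs) || !nrow(framePairs)) return(ledger)
  tb <- ledgerTable(ledger)
  for (r in seq_len(nrow(framePairs))) {
    i <- which(tb$mother_track == framePairs$mother_track[r] &
                 tb$bud_track == framePairs$bud_track[r])
    if (length(i)) {
      tb$psum[i] <- tb$psum[i] + framePairs$p[r]
      tb$count[i] <- tb$count[i] + 1L
    } else {
      tb <- rbind(tb, data.frame(
        mother_track = framePairs$mother_track[r],
        bud_track = framePairs$bud_track[r],
        psum = framePairs$p[r], count = 1L))
    }
  }
  new("LineageLedger", table = tb)
}

#' Assign each bud to the mother with the highest accumulated probability
#'
#' Only candidates observed jointly with the bud for at least
#' `minJointFrames` time points qualify; ties break by higher mean
#' probability, then by lower mother track id. Buds with no qualifying
#' candidate are left unassigned.
#'
#' @param ledger a [LineageLedger-class].
#' @param minJointFrames minimum joint observations (default 3).
#' @return data.frame(bud_track, mother_track, accumulated_p, joint_frames).
#' @export
assignMothers <- function(ledger, minJointFrames = 3L) {
  tb <- ledgerTable(ledger)
  out <- data.frame(bud_track = integer(), mother_track = integer(),
                    accumulated_p = numeric(), joint_frames = integer())
  for (b in sort(unique(tb$bud_track))) {
    cand <- tb[tb$bud_track == b & tb$count >= minJointFrames, ,
               drop = FALSE]
    if (!nrow(cand)) next
    cand$meanp <- cand$psum / cand$count
    cand <- cand[order(-cand$psum, -cand$meanp, cand$mother_track), ,
                 drop = FALSE]
    out <- rbind(out, data.frame(
      bud_track = b, mother_track = cand$mother_track[1L],
      accumulated_p = cand$psum[1L], joint_frames = cand$count[1L]))
  }
  out
}
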