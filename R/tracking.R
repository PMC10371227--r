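# Classifier-based cell tracking.
#
# Two gradient-boosted pairwise classifiers estimate the probability that
# an outline at the previous time point is the same cell as one at the
# current time point: classifier A uses only morphology (so it survives
# pivoting colonies), classifier B augments it with position (centroid
# distance and mask IoU). Predictions are aggregated over the last three
# time points of each track; frame assignment is an optimal one-to-one
# matching in which A decides wherever it separates the candidates and B
# breaks the ties A cannot see.

#' Morphological features of one cell
#'
#' Area, boundary perimeter, major/minor axis and eccentricity from second
#' moments, centroid, and the mean and sd of boundary radii about the
#' centroid. Translation leaves everything but the centroid unchanged.
#'
#' @param x a [SegmentedInstance-class] or a logical mask matrix.
#' @return named numeric vector (area, perimeter, major, minor, ecc, cy,
#'   cx, radMean, radSD).
#' @export
extractMorphFeatures <- function(x) {
  mask <- if (is(x, "SegmentedInstance")) instanceMask(x) else x != 0
  if (!any(mask)) stop("empty mask has no features")
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1L]); cx <- mean(idx[, 2L])
  dy <- idx[, 1L] - cy; dx <- idx[, 2L] - cx
  mu20 <- mean(dy^2); mu02 <- mean(dx^2); mu11 <- mean(dy * dx)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- max(tr - l1, 0)
  bnd <- which(maskBoundary(mask), arr.ind = TRUE)
  rad <- sqrt((bnd[, 1L] - cy)^2 + (bnd[, 2L] - cx)^2)
  c(area = sum(mask), perimeter = nrow(bnd),
    major = 2 * sqrt(l1), minor = 2 * sqrt(l2),
    ecc = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
    cy = cy, cx = cx, radMean = mean(rad), radSD = sd(rad))
}

#' Pairwise feature vector for two cells
#'
#' Absolute differences and log-ratios of the scale features plus the
#' eccentricity difference. With `withPosition = TRUE` (classifier B) the
#' centroid distance and, when masks are supplied, the mask IoU are
#' appended; both encode position and are withheld from classifier A so
#' that it stays robust to pivoting.
#'
#' @param fa,fb feature vectors from [extractMorphFeatures()].
#' @param withPosition append centroid distance (and IoU).
#' @param maskA,maskB optional masks for the IoU term.
#' @return named numeric vector.
#' @export
pairFeatures <- function(fa, fb, withPosition = FALSE, maskA = NULL,
                         maskB = NULL) {
  sc <- c("area", "perimeter", "major", "minor", "radMean")
  eps <- 0.1
  out <- c(setNames(abs(fa[sc] - fb[sc]), paste0("d_", sc)),
           setNames(log((fa[sc] + eps) / (fb[sc] + eps)),
                    paste0("lr_", sc)),
           d_ecc = abs(fa[["ecc"]] - fb[["ecc"]]),
           d_radSD = abs(fa[["radSD"]] - fb[["radSD"]]))
  if (withPosition) {
    dist <- sqrt((fa[["cy"]] - fb[["cy"]])^2 + (fa[["cx"]] - fb[["cx"]])^2)
    iou <- if (!is.null(maskA) && !is.null(maskB) &&
               (any(maskA & maskB) || any(maskA | maskB)))
      sum(maskA & maskB) / sum(maskA | maskB) else 0
    out <- c(out, dist = dist, iou = iou)
  }
  out
}

#' Build labelled same/different-cell pairs from a ground-truth movie
#'
#' For every pair of frames `gap` time points apart, all (previous,
#' current) cell pairs are labelled by whether they share a track.
#'
#' @param movie a [SimulatedMovie-class].
#' @param gaps frame gaps to include (1:3 spans the aggregation buffer).
#' @return list(XA, XB, y): feature matrices for classifiers A and B plus
#'   the 0/1 labels.
#' @export
makeTrackingPairs <- function(movie, gaps = 1:3) {
  frs <- frames(movie)
  XA <- NULL; XB <- NULL; y <- integer()
  for (g in gaps) for (t in seq_len(length(frs) - g)) {
    f1 <- frs[[t]]; f2 <- frs[[t + g]]
    if (!length(masks(f1)) || !length(masks(f2))) next
    fe1 <- lapply(masks(f1), extractMorphFeatures)
    fe2 <- lapply(masks(f2), extractMorphFeatures)
    for (i in seq_along(fe1)) for (j in seq_along(fe2)) {
      XA <- rbind(XA, pairFeatures(fe1[[i]], fe2[[j]]))
      XB <- rbind(XB, pairFeatures(fe1[[i]], fe2[[j]], TRUE,
                                   masks(f1)[[i]], masks(f2)[[j]]))
      y <- c(y, as.integer(trackLabels(f1)[i] == trackLabels(f2)[j]))
    }
  }
  list(XA = XA, XB = XB, y = y)
}

fitPairClassifier <- function(X, y, seed, nrounds = 60L) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 4L,
                  eta = 0.3, nthread = 1L, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = nrounds,
    verbose = 0)
}

#' Train the two tracking classifiers
#'
#' @param pairs output of [makeTrackingPairs()] (possibly concatenated over
#'   movies).
#' @param seed seed for reproducible boosting.
#' @return object of class `trackClassifiers` with members `A`
#'   (morphology-only) and `B` (morphology + position).
#' @export
trainTrackClassifiers <- function(pairs, seed = 1L) {
  if (length(unique(pairs$y)) < 2L)
    stop("need both same-cell and different-cell pairs")
  structure(list(
    A = fitPairClassifier(pairs$XA, pairs$y, seed),
    B = fitPairClassifier(pairs$XB, pairs$y, seed + 1L),
    featNamesA = colnames(pairs$XA), featNamesB = colnames(pairs$XB)),
    class = "trackClassifiers")
}

predictPair <- function(model, x) {
  as.numeric(stats::predict(model, matrix(x, nrow = 1L,
                                          dimnames = list(NULL, names(x)))))
}

#' Probability that two outlines are the same cell
#'
#' Classifier A (morphology only) is consulted first; if its verdict is
#' ambiguous (probability below `ambiguityP`) the position-augmented
#' classifier B decides.
#'
#' @param prev,curr [SegmentedInstance-class] objects or masks.
#' @param classifiers a `trackClassifiers` object.
#' @param ambiguityP deferral threshold on classifier A's probability.
#' @return probability in [0,1].
#' @export
trackProbability <- function(prev, curr, classifiers, ambiguityP = 0.75) {
  fp <- extractMorphFeatures(prev); fc <- extractMorphFeatures(curr)
  pA <- predictPair(classifiers$A, pairFeatures(fp, fc))
  if (pA >= ambiguityP) return(pA)
  mp <- if (is(prev, "SegmentedInstance")) instanceMask(prev) else prev != 0
  mc <- if (is(curr, "SegmentedInstance")) instanceMask(curr) else curr != 0
  predictPair(classifiers$B, pairFeatures(fp, fc, TRUE, mp, mc))
}

#' Create an empty tracker state
#' @return object of class `trackerState`.
#' @export
newTrackerState <- function() {
  structure(list(tracks = list(), nextId = 1L, time = 0L),
            class = "trackerState")
}

instMask <- function(x) if (is(x, "SegmentedInstance")) instanceMask(x) else
  x != 0

#' Track one frame of segmented instances
#'
#' Aggregated pairwise probabilities: every active track contributes the
#' mean probability over its buffered instances from the last three time
#' points, for both classifiers (PA: morphology only; PB: with position).
#' A link is admissible when either classifier clears `pMin`, so a
#' confident morphology match survives a pivot and a confident positional
#' match survives a transient segmentation glitch. Among admissible links
#' the optimal one-to-one assignment maximises PA + `weightB` * PB:
#' classifier A decides wherever it separates the candidates and classifier
#' B breaks the ties A cannot see (e.g. identically sized sister buds).
#' Unmatched instances open new tracks; tracks unmatched for more than
#' `lostPatience` frames are closed.
#'
#' @param state a `trackerState` (from [newTrackerState()] or a previous
#'   call).
#' @param instances list of [SegmentedInstance-class] (or masks).
#' @param classifiers a `trackClassifiers` object.
#' @param pMin minimum probability for a link.
#' @param lostPatience frames a track may go unseen before closing.
#' @param weightB weight of classifier B in the tie-breaking score.
#' @return list(state, labels): updated state and the per-instance track
#'   labels.
#' @export
trackFrame <- function(state, instances, classifiers, pMin = 0.5,
                       lostPatience = 2L, weightB = 0.5) {
  state$time <- state$time + 1L
  n <- length(instances)
  feats <- lapply(instances, extractMorphFeatures)
  msks <- lapply(instances, instMask)
  act <- which(vapply(state$tracks, function(tr) tr$active, logical(1)))
  m <- length(act)
  labels <- rep(NA_integer_, n)
  if (n && m) {
    PA <- matrix(0, n, m); PB <- matrix(0, n, m)
    for (k in seq_len(m)) {
      buf <- state$tracks[[act[k]]]$buffer
      for (j in seq_len(n)) {
        PA[j, k] <- mean(vapply(buf, function(en)
          predictPair(classifiers$A, pairFeatures(en$feat, feats[[j]])),
          numeric(1)))
        PB[j, k] <- mean(vapply(buf, function(en)
          predictPair(classifiers$B,
                      pairFeatures(en$feat, feats[[j]], TRUE, en$mask,
                                   msks[[j]])), numeric(1)))
      }
    }
    admissible <- PA >= pMin | PB >= pMin
    S <- PA + weightB * PB
    cost <- -log(pmax(S / (1 + weightB), 1e-12))
    cost[!admissible] <- 1e6
    asg <- solveAssignment(cost)
    for (j in seq_len(n)) {
      k <- asg[j]
      if (!is.na(k) && admissible[j, k])
        labels[j] <- state$tracks[[act[k]]]$id
    }
  }
  # update matched tracks, open new ones
  for (j in seq_len(n)) {
    if (is.na(labels[j])) {
      id <- state$nextId; state$nextId <- state$nextId + 1L
      state$tracks[[length(state$tracks) + 1L]] <- list(
        id = id, buffer = list(), lastSeen = state$time, active = TRUE)
      labels[j] <- id
    }
    ti <- which(vapply(state$tracks, function(tr) tr$id == labels[j],
                       logical(1)))
    tr <- state$tracks[[ti]]
    tr$buffer <- c(tr$buffer, list(list(time = state$time,
                                        feat = feats[[j]],
                                        mask = msks[[j]])))
    if (length(tr$buffer) > 3L)
      tr$buffer <- tr$buffer[(length(tr$buffer) - 2L):length(tr$buffer)]
    tr$lastSeen <- state$time
    state$tracks[[ti]] <- tr
  }
  for (ti in seq_along(state$tracks)) {
    tr <- state$tracks[[ti]]
    if (tr$active && state$time - tr$lastSeen > lostPatience)
      state$tracks[[ti]]$active <- FALSE
  }
  list(state = state, labels = labels)
}

#' Track a whole movie of per-frame instance lists
#'
#' @param instanceLists list (over time) of lists of
#'   [SegmentedInstance-class] or masks.
#' @param classifiers a `trackClassifiers` object.
#' @param dim image (H, W); inferred from the first mask when omitted.
#' @param ... passed to [trackFrame()].
#' @return list of [AnnotatedFrame-class] carrying the assigned track
#'   labels.
#' @export
trackInstances <- function(instanceLists, classifiers, dim = NULL, ...) {
  state <- newTrackerState()
  out <- vector("list", length(instanceLists))
  for (t in seq_along(instanceLists)) {
    res <- trackFrame(state, instanceLists[[t]], classifiers, ...)
    state <- res$state
    mk <- lapply(instanceLists[[t]], instMask)
    if (is.null(dim) && length(mk)) dim <- base::dim(mk[[1L]])
    out[[t]] <- AnnotatedFrame(mk, res$labels, dim = dim)
  }
  out
}

CLASSIFIER_BUNDLE_VERSION <- "budwatch-classifiers-1"

#' Save or load a classifier bundle
#'
#' Serialises the tracking classifiers (and optionally the mother-bud
#' classifier) with a schema version tag, so a pipeline can be rerun with
#' the exact classifiers of an earlier analysis.
#'
#' @param classifiers list with elements `track` (a `trackClassifiers`)
#'   and optionally `motherBud` (a `motherBudClassifier`).
#' @param path file path.
#' @return `path` invisibly (`saveClassifiers`); the classifier list
#'   (`loadClassifiers`).
#' @export
saveClassifiers <- function(classifiers, path) {
  stopifnot(inherits(classifiers$track, "trackClassifiers"))
  saveRDS(list(version = CLASSIFIER_BUNDLE_VERSION,
               classifiers = classifiers), path)
  invisible(path)
}

#' @rdname saveClassifiers
#' @export
loadClassifiers <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CLASSIFIER_BUNDLE_VERSION))
    stop("unsupported classifier bundle version: ", obj$version)
  obj$classifiers
}
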