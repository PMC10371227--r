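# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

fixtureEnv <- new.env(parent = emptyenv())

fixtureMovie <- function() {
  if (is.null(fixtureEnv$movie))
    fixtureEnv$movie <- simulateColony(
      SimParams(nTimepoints = 20L, seed = 73L), render = FALSE)
  fixtureEnv$movie
}

fixtureSpec <- function() {
  if (is.null(fixtureEnv$spec))
    fixtureEnv$spec <- optimizeSizeBoundaries(frames(fixtureMovie()))
  fixtureEnv$spec
}

# tracking + mother-bud classifiers trained once on independent movies
fixtureClassifiers <- function() {
  if (is.null(fixtureEnv$cls)) {
    mvs <- list(
      simulateColony(SimParams(nTimepoints = 22L, seed = 577L,
                               pivotProb = 0.15), render = FALSE),
      simulateColony(SimParams(nTimepoints = 28L, seed = 578L,
                               nMothers = 3L, washoutProb = 0.03),
                     render = FALSE),
      simulateColony(SimParams(nTimepoints = 30L, seed = 579L),
                     render = FALSE))
    tp <- lapply(mvs, makeTrackingPairs)
    pairs <- list(XA = do.call(rbind, lapply(tp, `[[`, "XA")),
                  XB = do.call(rbind, lapply(tp, `[[`, "XB")),
                  y = unlist(lapply(tp, `[[`, "y")))
    mbx <- lapply(mvs, function(mv)
      makeMotherBudExamples(mv, optimizeSizeBoundaries(frames(mv))))
    mb <- list(X = do.call(rbind, lapply(mbx, `[[`, "X")),
               y = unlist(lapply(mbx, `[[`, "y")))
    fixtureEnv$cls <- list(
      track = trainTrackClassifiers(pairs, seed = 11L),
      motherBud = trainMotherBudClassifier(mb, seed = 12L))
  }
  fixtureEnv$cls
}

# a rasterised disc of radius r (pixel centres within r of the centre)
discMask <- function(r, pad = 4L) {
  n <- 2L * ceiling(r) + 2L * pad + 1L
  ctr <- (n + 1) / 2
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix(FALSE, n, n)
  m[(xy$row - ctr)^2 + (xy$col - ctr)^2 <= r^2] <- TRUE
  m
}
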