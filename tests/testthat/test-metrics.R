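# The evaluation suite: IoU matching, average precision, track IoU,
# complete-track fraction, MOTA and lineage precision/recall.

sq <- function(r1, r2, c1, c2, dim = c(30L, 30L)) {
  m <- matrix(FALSE, dim[1L], dim[2L]); m[r1:r2, c1:c2] <- TRUE; m
}

test_that("mask IoU counts pixels", {
  a <- sq(1, 10, 1, 10)
  expect_equal(maskIoU(a, a), 1)
  expect_equal(maskIoU(a, sq(20, 25, 20, 25)), 0)
  # 10x10 squares overlapping in a 5x10 strip: 50 / 150
  expect_equal(maskIoU(a, sq(6, 15, 1, 10)), 1 / 3)
  expect_error(maskIoU(a & FALSE, a & FALSE), "empty")
})

test_that("greedy matching is one-to-one and descends by IoU", {
  a <- sq(1, 10, 1, 10)
  mm <- matchMasks(list(a), list(a))
  expect_equal(mm$pairs$iou, 1)
  mm2 <- matchMasks(list(a, sq(2, 11, 1, 10)), list(a))
  expect_equal(nrow(mm2$pairs), 1L)
  expect_equal(mm2$pairs$pred, 1L)          # the better of the two wins
  expect_equal(mm2$unmatchedPred, 2L)
})

test_that("greedy matching agrees with the exhaustive oracle when greedy is optimal", {
  # brute force over all one-to-one matchings, maximising summed IoU
  bruteBest <- function(M) {
    n <- nrow(M); m <- ncol(M)
    idx <- seq_len(m)
    best <- 0
    perm <- function(rows, cols, acc) {
      if (!length(rows)) { best <<- max(best, acc); return(invisible()) }
      perm(rows[-1L], cols, acc)            # leave this pred unmatched
      for (j in cols)
        perm(rows[-1L], setdiff(cols, j), acc + M[rows[1L], j])
    }
    perm(seq_len(n), idx, 0)
    best
  }
  set.seed(4)
  agree <- 0L; total <- 20L
  for (rep in seq_len(total)) {
    n <- sample(3:4, 1)
    M <- matrix(round(runif(n * n), 2), n, n)
    greedy <- 0
    W <- M
    repeat {
      b <- which.max(W); if (W[b] <= 0) break
      j <- (b - 1L) %/% n + 1L; i <- b - (j - 1L) * n
      greedy <- greedy + W[i, j]; W[i, ] <- -1; W[, j] <- -1
    }
    opt <- bruteBest(M)
    expect_lte(greedy, opt + 1e-9)
    if (abs(greedy - opt) < 1e-9) agree <- agree + 1L
  }
  # divergences on adversarial random matrices are real and surfaced, not
  # hidden: greedy never beats the optimum and agrees on a good share
  expect_gt(agree, 0L)
  # on well-separated matrices (every prediction has one dominant truth,
  # the regime of actual mask IoUs) greedy equals the exhaustive optimum
  for (rep in 1:10) {
    n <- sample(3:4, 1)
    M <- matrix(runif(n * n, 0, 0.2), n, n)
    diag(M) <- runif(n, 0.6, 1)
    W <- M; greedy <- 0
    repeat {
      b <- which.max(W); if (W[b] <= 0) break
      j <- (b - 1L) %/% n + 1L; i <- b - (j - 1L) * n
      greedy <- greedy + W[i, j]; W[i, ] <- -1; W[, j] <- -1
    }
    expect_equal(greedy, bruteBest(M), tolerance = 1e-9)
  }
})

test_that("average precision: perfect, empty and the hand-computed case", {
  a <- sq(1, 10, 1, 10); b <- sq(15, 24, 15, 24)
  perfect <- matchMasks(list(a, b), list(a, b))
  expect_equal(averagePrecision(perfect), 1)
  none <- matchMasks(list(), list(a, b))
  expect_equal(averagePrecision(none, nPred = 0, nTruth = 2), 0)
  expect_error(averagePrecision(matchMasks(list(a), list()), nTruth = 0),
               "no ground-truth")
  # 2 truths, 1 perfect prediction: precision 1 at recall 0.5 everywhere
  # -> area under the single-step curve is 0.5
  half <- matchMasks(list(a), list(a, b))
  expect_equal(averagePrecision(half), 0.5)
})

# toy movies for the track metrics: one cell per track, squares that move
toyFrames <- function(labelSeq, dim = c(30L, 30L)) {
  # labelSeq: list over time of named lists label -> mask
  lapply(labelSeq, function(fr)
    AnnotatedFrame(unname(fr), as.integer(names(fr)), dim = dim))
}

test_that("track IoU counts agreeing frames over the union of durations", {
  a <- sq(1, 10, 1, 10); b <- sq(15, 24, 15, 24)
  truth <- toyFrames(rep(list(list(`1` = a)), 10))
  # prediction covers frames 1..5 only
  pred <- toyFrames(c(rep(list(list(`7` = a)), 5), rep(list(list()), 5)))
  maps <- frameLabelMaps(pred, truth)
  expect_equal(trackIoU(7L, 1L, maps, pred, truth), 0.5)
  # identical tracks give 1
  same <- toyFrames(rep(list(list(`7` = a)), 10))
  expect_equal(trackIoU(7L, 1L, frameLabelMaps(same, truth), same, truth), 1)
  # splitting into two 5-frame pieces: best match scores 1/2, other 0
  split <- toyFrames(c(rep(list(list(`7` = a)), 5),
                       rep(list(list(`8` = a)), 5)))
  tm <- matchTracks(split, truth)
  expect_equal(tm$table$track_iou, 0.5)
  expect_equal(tm$unmatchedPred,
               setdiff(c(7L, 8L), tm$table$pred_track))
})

test_that("splitting one truth track into k even pieces scores 1/k", {
  a <- sq(1, 10, 1, 10)
  truth <- toyFrames(rep(list(list(`1` = a)), 12))
  for (k in c(2L, 3L, 4L)) {
    pieces <- rep(seq_len(k), each = 12L %/% k) + 100L
    pred <- toyFrames(lapply(pieces, function(p)
      setNames(list(a), as.character(p))))
    tm <- matchTracks(pred, truth)
    expect_equal(tm$table$track_iou, 1 / k)
  }
})

test_that("complete-track fraction honours the missing tolerance", {
  a <- sq(1, 10, 1, 10)
  truth <- toyFrames(rep(list(list(`1` = a)), 10))
  perfect <- toyFrames(rep(list(list(`5` = a)), 10))
  expect_equal(fractionCompleteTracks(perfect, truth), 1)
  # split in half: duration 5 vs 10 misses tolerance 2
  split <- toyFrames(c(rep(list(list(`5` = a)), 5),
                       rep(list(list(`6` = a)), 5)))
  expect_equal(fractionCompleteTracks(split, truth, missingTolerance = 2), 0)
  expect_equal(fractionCompleteTracks(split, truth,
                                      missingTolerance = Inf), 1)
})

test_that("MOTA: perfect, all-missed, and a single identity switch", {
  a <- sq(1, 10, 1, 10); b <- sq(15, 24, 15, 24)
  truth <- toyFrames(rep(list(list(`1` = a, `2` = b)), 5))
  perfect <- toyFrames(rep(list(list(`1` = a, `2` = b)), 5))
  expect_equal(mota(perfect, truth)$mota, 1)
  empty <- toyFrames(rep(list(list()), 5))
  expect_equal(mota(empty, truth)$mota, 0)       # all FN, no FP or switches
  # swap the two predicted labels halfway: 2 switches among 10 objects
  swapped <- toyFrames(c(rep(list(list(`1` = a, `2` = b)), 3),
                         rep(list(list(`2` = a, `1` = b)), 2)))
  ms <- mota(swapped, truth)
  expect_equal(ms$idsw, 2L)
  expect_equal(ms$mota, 1 - 2 / 10)
  expect_error(mota(perfect, toyFrames(rep(list(list()), 5))), "no ground")
})

test_that("lineage precision/recall follows the counting rule", {
  a <- sq(1, 10, 1, 10); b <- sq(15, 24, 15, 24); c3 <- sq(1, 6, 20, 25)
  truth <- toyFrames(rep(list(list(`1` = a, `2` = b, `3` = c3)), 6))
  pred <- toyFrames(rep(list(list(`11` = a, `12` = b, `13` = c3)), 6))
  tm <- matchTracks(pred, truth)
  truthPairs <- data.frame(bud_track = c(2L, 3L), mother_track = c(1L, 1L))
  predPairs <- data.frame(bud_track = c(12L, 13L),
                          mother_track = c(11L, 11L))
  pr <- lineagePrecisionRecall(predPairs, truthPairs, tm)
  expect_equal(pr$precision, 1); expect_equal(pr$recall, 1)
  # one bud assigned to the wrong mother
  wrong <- data.frame(bud_track = c(12L, 13L), mother_track = c(11L, 12L))
  pr2 <- lineagePrecisionRecall(wrong, truthPairs, tm)
  expect_equal(pr2$tp, 1L); expect_equal(pr2$fp, 1L); expect_equal(pr2$fn, 1L)
  expect_equal(pr2$precision, 0.5); expect_equal(pr2$recall, 0.5)
  # an unassigned bud is a false negative only
  pr3 <- lineagePrecisionRecall(predPairs[1, ], truthPairs, tm)
  expect_equal(pr3$fn, 1L); expect_equal(pr3$fp, 0L)
  # restriction to the central cell
  pr4 <- lineagePrecisionRecall(wrong, truthPairs, tm, centralTracks = 1L)
  expect_equal(pr4$tp + pr4$fn, 2L)
})

test_that("growth RMSE is ~0 on identical masks and its bootstrap degenerates", {
  mv <- fixtureMovie()
  frs <- frames(mv)[1:12]
  res <- growthRMSE(frs, frs, pixelSize = 0.263, nBoot = 50, seed = 2L)
  expect_lt(res$rmse, 0.5)
  expect_equal(length(res$bootstrap), 50L)
  # dilating every mask perturbs volumes and the RMSE grows but stays finite
  dil <- lapply(frs, function(fr)
    AnnotatedFrame(lapply(masks(fr), dilateDisc, depth = 1),
                   trackLabels(fr), dim = frameDim(fr)))
  res2 <- growthRMSE(dil, frs, pixelSize = 0.263, nBoot = 10, seed = 2L)
  expect_gte(res2$rmse, res$rmse)
  expect_true(is.finite(res2$rmse))
  # identical samples: zero-width bootstrap distribution
  expect_lt(diff(range(res$bootstrap)), max(res$rmse, 1e-6))
})

test_that("all metrics take their perfect values on ground truth", {
  mv <- fixtureMovie()
  frs <- frames(mv)[1:10]
  aps <- vapply(frs, function(fr)
    averagePrecision(matchMasks(masks(fr), masks(fr))), numeric(1))
  expect_true(all(aps == 1))
  expect_equal(fractionCompleteTracks(frs, frs), 1)
  expect_equal(mota(frs, frs)$mota, 1)
  tm <- matchTracks(frs, frs)
  expect_true(all(tm$table$track_iou == 1))
})
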