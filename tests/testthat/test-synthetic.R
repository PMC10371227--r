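# The synthetic trapped-colony generator: determinism, growth laws,
# degenerate cases, overlap control and bookkeeping invariants.

test_that("equal parameters give bit-identical movies, images included", {
  p <- SimParams(nTimepoints = 6L, seed = 19L)
  m1 <- simulateColony(p)
  m2 <- simulateColony(p)
  expect_identical(lapply(frames(m1), masks), lapply(frames(m2), masks))
  expect_identical(trueVolumes(m1), trueVolumes(m2))
  expect_identical(images(m1), images(m2))
})

test_that("no mothers means empty frames and no tracks", {
  mv <- simulateColony(SimParams(nMothers = 0L, nTimepoints = 4L),
                       render = FALSE)
  expect_length(frames(mv), 4L)
  expect_true(all(vapply(frames(mv), function(f) length(masks(f)) == 0L,
                         logical(1))))
  expect_equal(nrow(trueVolumes(mv)), 0L)
})

test_that("zero growth rate is a fixed point: constant mask and volume", {
  mv <- simulateColony(SimParams(nMothers = 1L, nTimepoints = 6L,
                                 budGrowthRateRange = c(0, 0), seed = 5L),
                       render = FALSE)
  mk <- lapply(frames(mv), masks)
  expect_true(all(vapply(mk, length, integer(1)) == 1L))
  for (t in 2:6) expect_identical(mk[[t]], mk[[1L]])
  expect_equal(length(unique(trueVolumes(mv)$volume)), 1L)
})

test_that("exponential growth matches its closed form exactly", {
  p <- SimParams(nMothers = 1L, nTimepoints = 10L,
                 growthLaw = "exponential",
                 budGrowthRateRange = c(0.4, 0.4), seed = 2L)
  mv <- simulateColony(p, render = FALSE)
  tv <- trueVolumes(mv)
  buds <- setdiff(unique(tv$track), 1L)
  expect_gt(length(buds), 0L)
  dtH <- p@samplingInterval / 60
  for (b in buds) {
    v <- tv$volume[tv$track == b]
    pre <- v[seq_len(min(length(v), 5L))]   # pre-cytokinesis stretch
    if (length(pre) > 1L)
      expect_equal(pre[-1L] / pre[-length(pre)],
                   rep(exp(0.4 * dtH), length(pre) - 1L), tolerance = 1e-10)
  }
})

test_that("bud volumes are positive and non-decreasing before cytokinesis", {
  mv <- fixtureMovie()
  tv <- trueVolumes(mv)
  cyt <- trueCytokinesis(mv)
  for (b in lineage(mv)$bud_track) {
    sel <- tv[tv$track == b, ]
    expect_true(all(sel$volume > 0))
    tc <- cyt$cyto_t[match(b, cyt$bud_track)]
    pre <- if (is.na(tc)) sel$volume else sel$volume[sel$timeIdx < tc]
    if (length(pre) > 1L) expect_true(all(diff(pre) >= 0))
  }
})

test_that("every bud's first frame follows its mother's presence and labels are tracks", {
  mv <- fixtureMovie()
  firstSeen <- list()
  for (t in seq_along(frames(mv))) {
    fr <- frames(mv)[[t]]
    expect_false(anyDuplicated(trackLabels(fr)) > 0)
    for (lb in trackLabels(fr))
      if (is.null(firstSeen[[as.character(lb)]]))
        firstSeen[[as.character(lb)]] <- t
  }
  lin <- lineage(mv)
  for (k in seq_len(nrow(lin)))
    expect_gte(firstSeen[[as.character(lin$bud_track[k])]],
               firstSeen[[as.character(lin$mother_track[k])]])
})

test_that("mean pairwise overlap is non-decreasing in overlapBias", {
  meanOverlap <- function(bias, seed) {
    mv <- simulateColony(SimParams(nTimepoints = 12L, overlapBias = bias,
                                   seed = seed), render = FALSE)
    tot <- 0; n <- 0
    for (fr in frames(mv)) {
      mk <- masks(fr)
      if (length(mk) < 2L) next
      for (i in seq_len(length(mk) - 1L)) for (j in (i + 1L):length(mk)) {
        tot <- tot + sum(mk[[i]] & mk[[j]]); n <- n + 1
      }
    }
    if (n) tot / n else 0
  }
  biases <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(biases, function(b)
    mean(vapply(1:10, function(s) meanOverlap(b, 900L + s), numeric(1))),
    numeric(1))
  expect_gte(cor(biases, means, method = "spearman"), 0)
})

test_that("track terminations are washouts plus final-frame survivors", {
  mv <- simulateColony(SimParams(nTimepoints = 30L, seed = 41L,
                                 washoutProb = 0.05), render = FALSE)
  tv <- trueVolumes(mv)
  lastSeen <- tapply(tv$timeIdx, tv$track, max)
  TT <- length(frames(mv))
  survivors <- sum(lastSeen == TT)
  washed <- sum(lastSeen < TT)
  expect_equal(survivors + washed, length(unique(tv$track)))
})

test_that("renderer: empty frame is pure noise around the background level", {
  p <- SimParams(nMothers = 0L, nTimepoints = 1L, noiseSD = 0.05, seed = 3L)
  fr <- AnnotatedFrame(dim = p@imageShape)
  img <- renderBrightfieldStack(fr, p, seed = 3L)
  expect_equal(dim(img), c(96L, 96L, 5L))
  expect_equal(mean(img), 0.5, tolerance = 0.01)
})

test_that("renderer: noiseless single cell has dark rim and bright interior", {
  p <- SimParams(nMothers = 1L, nTimepoints = 1L, nZ = 1L, noiseSD = 0,
                 budGrowthRateRange = c(0, 0), seed = 7L)
  mv <- simulateColony(p)
  img <- images(mv)[[1L]][, , 1L]
  m <- masks(frames(mv)[[1L]])[[1L]]
  rim <- m & !erodeDisc(m, 1.4)
  core <- erodeDisc(m, 3)
  bgLevel <- median(img[!dilateDisc(m, 6)])
  expect_lt(min(img[rim]), bgLevel)          # rim darker than background
  expect_gt(mean(img[core]), bgLevel)        # interior brighter
})

test_that("renderer is deterministic for equal seeds and differs otherwise", {
  p <- SimParams(nTimepoints = 1L, seed = 13L)
  fr <- frames(simulateColony(p, render = FALSE))[[1L]]
  expect_identical(renderBrightfieldStack(fr, p, seed = 5L),
                   renderBrightfieldStack(fr, p, seed = 5L))
  expect_false(identical(renderBrightfieldStack(fr, p, seed = 5L),
                         renderBrightfieldStack(fr, p, seed = 6L)))
})

test_that("invalid parameters are rejected", {
  expect_error(SimParams(pivotProb = 1.5), "probability")
  expect_error(SimParams(nZ = 3L), "nZ")
  expect_error(SimParams(imageShape = c(20L, 20L),
                         motherRadiusRange = c(15, 18)), "exceeds")
  expect_error(SimParams(growthLaw = "bilinear"), "growthLaw")
})

test_that("ground truth emit/read round-trips losslessly", {
  mv <- simulateColony(SimParams(nTimepoints = 6L, seed = 23L,
                                 nMothers = 2L))
  dir <- withr::local_tempdir()
  emitGroundTruth(mv, dir)
  mv2 <- readGroundTruth(dir)
  expect_identical(lapply(frames(mv), masks), lapply(frames(mv2), masks))
  expect_identical(lapply(frames(mv), trackLabels),
                   lapply(frames(mv2), trackLabels))
  expect_identical(lapply(frames(mv), motherPairs),
                   lapply(frames(mv2), motherPairs))
  expect_equal(trueVolumes(mv), trueVolumes(mv2), tolerance = 1e-12)
  expect_equal(lineage(mv), lineage(mv2))
  # tracks.csv carries one row per (time, track); cytokinesis time in lineage.csv
  tracks <- read.csv(file.path(dir, "tracks.csv"))
  expect_setequal(unique(tracks$track), unique(trueVolumes(mv)$track))
  lin <- read.csv(file.path(dir, "lineage.csv"))
  cyt <- trueCytokinesis(mv)
  if (nrow(cyt))
    expect_equal(lin$cytokinesis_t[match(cyt$bud_track, lin$bud_track)],
                 cyt$cyto_t)
})
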