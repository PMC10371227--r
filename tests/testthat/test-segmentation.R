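# Instance segmentation: seeds, erosion reversal, radial splines,
# de-duplication and the composed per-frame pipeline.

zeroTargets <- function(dim = c(32L, 32L)) {
  SemanticTargets(array(0, c(dim, 8L)), binary = FALSE)
}

test_that("seed extraction thresholds and 4-connectivity behave", {
  ts <- zeroTargets()
  expect_identical(extractSeeds(ts), list())
  ch <- channels(ts)
  ch[5:10, 5:10, "interior_M"] <- 0.9
  ch[20:26, 20:26, "interior_M"] <- 0.8
  seeds <- extractSeeds(SemanticTargets(ch, binary = FALSE))
  expect_length(seeds, 2L)
  expect_true(all(vapply(seeds, function(s) s$category == "M", logical(1))))
  # a 1 px gap splits a blob into two seeds (4-connected components)
  ch2 <- channels(zeroTargets())
  ch2[5:15, 5:9, "interior_S"] <- 1
  ch2[5:15, 11:15, "interior_S"] <- 1
  expect_length(extractSeeds(SemanticTargets(ch2, binary = FALSE)), 2L)
  # components below the minimum seed area are dropped
  ch3 <- channels(zeroTargets())
  ch3[5:6, 5:6, "interior_L"] <- 1
  expect_length(extractSeeds(SemanticTargets(ch3, binary = FALSE),
                             minSeedArea = 5), 0L)
})

test_that("erosion reversal follows the closed form on discs", {
  spec <- SizeCategorySpec(c(100, 300), erosionDepth = c(1, 2, 3))
  seed <- discMask(8)
  grown <- reverseErosion(seed, "M", spec)          # dilate by 2
  # continuum closed form is pi*10^2; the lattice dilation lands within 6%
  expect_lt(abs(sum(grown) - pi * 100) / (pi * 100), 0.06)
  expect_true(all(grown[seed]))
  expect_identical(reverseErosion(seed, "M",
                                  SizeCategorySpec(c(100, 300),
                                                   erosionDepth = c(0, 0, 0))),
                   seed)
})

test_that("a perfect circular edge map is recovered within 5% area", {
  dimHW <- c(40L, 40L)
  truth <- rasteriseEllipse(dimHW, c(20, 20), 10, 10)
  edge <- budwatch:::maskBoundary(truth) * 1
  grown <- erodeDisc(truth, 2)                # imperfect grown mask
  grown <- dilateDisc(grown, 2)
  for (nr in c(4L, 6L, 8L)) {
    spl <- fitRadialSpline(grown, edge, NULL, nRays = nr)
    m <- rasteriseSpline(spl, dimHW)
    expect_lt(abs(sum(m) - pi * 100) / (pi * 100), 0.05)
  }
})

test_that("zero edge evidence falls back to the grown-mask boundary", {
  grown <- discMask(7)
  spl <- fitRadialSpline(grown, matrix(0, nrow(grown), ncol(grown)), NULL,
                         nRays = 6L)
  expect_equal(spl@knotRadii, rep(spl@knotRadii[1L], 6L), tolerance = 0.1)
  m <- rasteriseSpline(spl, dim(grown))
  expect_gte(maskIoU(m, grown), 0.9)
})

test_that("an elliptical cell from oracle maps is recovered at IoU >= 0.85", {
  dimHW <- c(48L, 48L)
  truth <- rasteriseEllipse(dimHW, c(24, 24), 12, 8, 0.4)
  fr <- AnnotatedFrame(list(truth), 1L)
  spec <- SizeCategorySpec(c(50, 200), erosionDepth = c(1, 2, 3))
  tg <- oraclePredict(fr, spec)
  inst <- segmentFrame(tg, spec)
  expect_length(inst, 1L)
  expect_gte(maskIoU(instanceMask(inst[[1L]]), truth), 0.85)
  expect_equal(sizeCategory(inst[[1L]]), "L")
})

test_that("duplicate resolution keeps the highest score and allows true overlap", {
  mk1 <- discMask(6)
  inst <- function(mask, score, cat = "M")
    new("SegmentedInstance",
        spline = new("RadialSpline", centre = c(10, 10),
                     knotAngles = c(0, pi), knotRadii = c(6, 6)),
        mask = mask, category = cat, score = score)
  a <- inst(mk1, 0.9); b <- inst(mk1, 0.8)
  kept <- resolveDuplicates(list(b, a))
  expect_length(kept, 1L)
  expect_equal(instanceScore(kept[[1L]]), 0.9)
  # three mutually identical instances -> exactly one survives (brute force
  # over keep orders gives the same: any order keeps exactly the first)
  expect_length(resolveDuplicates(list(a, b, inst(mk1, 0.7))), 1L)
  # mother/bud with small IoU both survive
  m2 <- matrix(FALSE, nrow(mk1), ncol(mk1)); m2[1:7, 1:7] <- TRUE
  expect_lt(maskIoU(mk1, m2), 0.5)
  expect_length(resolveDuplicates(list(a, inst(m2, 0.6, "S"))), 2L)
})

test_that("overlapping mother and bud are both recovered, unlike plain components", {
  mv <- fixtureMovie()
  spec <- fixtureSpec()
  fr <- Find(function(f) nrow(motherPairs(f)) > 0, frames(mv))
  tg <- oraclePredict(fr, spec)
  inst <- segmentFrame(tg, spec)
  mm <- matchMasks(lapply(inst, instanceMask), masks(fr))
  expect_equal(nrow(mm$pairs), length(masks(fr)))
  expect_true(all(mm$pairs$iou >= 0.7))
  # the naive approach merges the overlapping pair into one component
  union <- Reduce(`|`, masks(fr))
  expect_lt(max(budwatch:::labelComponents(union)), length(masks(fr)))
})

test_that("empty maps segment to an empty instance list", {
  expect_identical(segmentFrame(zeroTargets(), fixtureSpec()), list())
})

test_that("blurred oracle maps keep the instance count", {
  mv <- fixtureMovie(); spec <- fixtureSpec()
  fr <- frames(mv)[[14L]]
  n0 <- length(segmentFrame(oraclePredict(fr, spec, sigma = 0), spec))
  n1 <- length(segmentFrame(oraclePredict(fr, spec, sigma = 1), spec))
  expect_equal(n0, length(masks(fr)))
  expect_equal(n1, n0)
})

test_that("rasterised splines are star-convex about their centre", {
  mv <- fixtureMovie(); spec <- fixtureSpec()
  fr <- frames(mv)[[16L]]
  inst <- segmentFrame(oraclePredict(fr, spec, sigma = 1), spec,
                       trustPx = 0)   # force the rasterised spline masks
  for (ins in inst) {
    spl <- instanceSpline(ins)
    m <- instanceMask(ins)
    idx <- which(m, arr.ind = TRUE)
    set.seed(1)
    for (k in sample(nrow(idx), min(40, nrow(idx)))) {
      # every point on the segment centre -> pixel stays inside the mask
      for (f in seq(0.1, 0.9, by = 0.2)) {
        p <- round(spl@centre + f * (idx[k, ] - spl@centre))
        expect_true(m[p[1L], p[2L]])
      }
    }
  }
})

test_that("instance scores are the mean interior probability under the mask", {
  mv <- fixtureMovie(); spec <- fixtureSpec()
  tg <- oraclePredict(frames(mv)[[10L]], spec)
  inst <- segmentFrame(tg, spec)
  for (ins in inst) {
    ch <- semanticChannel(tg, paste0("interior_", sizeCategory(ins)))
    expect_equal(instanceScore(ins), mean(ch[instanceMask(ins)]))
  }
})
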