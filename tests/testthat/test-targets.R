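# Target generation: size categories, boundary optimisation, erosion with
# guard, overlap and bud-neck channels, and the full eight-channel stack.

twoCellFrame <- function(dim = c(48L, 48L), shift = 10L) {
  # a 50 px^2 cell overlapping a ~500 px^2 cell
  small <- matrix(FALSE, dim[1L], dim[2L])
  small[20:26, 18:24] <- TRUE            # 49 px
  big <- rasteriseEllipse(dim, c(24, 24 + shift), 13, 12)
  AnnotatedFrame(list(small, big), c(1L, 2L))
}

test_that("size categories use half-open intervals on the full area", {
  spec <- SizeCategorySpec(c(100, 600))
  expect_equal(assignSizeCategory(10, spec), "S")
  expect_equal(assignSizeCategory(100, spec), "M")     # boundary goes up
  expect_equal(assignSizeCategory(599.5, spec), "M")
  expect_equal(assignSizeCategory(600, spec), "L")
  expect_equal(assignSizeCategory(1e6, spec), "L")
  m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE
  expect_equal(assignSizeCategory(m, spec), "S")
  expect_error(assignSizeCategory(matrix(FALSE, 3, 3), spec), "empty")
})

test_that("boundary optimisation separates overlapping size classes", {
  fr <- twoCellFrame()
  areas <- sort(vapply(masks(fr), sum, numeric(1)))
  spec <- optimizeSizeBoundaries(list(fr), nQuantiles = 20L)
  # exhaustive oracle: any boundary strictly between the two areas zeroes
  # the within-category overlap
  expect_gt(spec@boundaries[1L], areas[1L])
  expect_lte(spec@boundaries[1L], areas[2L])
  expect_equal(budwatch:::withinCategoryOverlap(list(fr), spec@boundaries), 0)
})

test_that("with no overlaps anywhere ties break to the area terciles", {
  m1 <- matrix(FALSE, 40, 40); m1[2:6, 2:6] <- TRUE
  m2 <- matrix(FALSE, 40, 40); m2[20:29, 20:29] <- TRUE
  m3 <- matrix(FALSE, 40, 40); m3[2:16, 20:34] <- TRUE
  fr <- AnnotatedFrame(list(m1, m2, m3), 1:3)
  spec <- optimizeSizeBoundaries(list(fr))
  areas <- c(25, 100, 225)
  terc <- quantile(areas, c(1, 2) / 3, names = FALSE)
  expect_equal(spec@boundaries, terc)
})

test_that("three-cell case: the chosen boundary isolates the overlapping pair", {
  # areas ~50 / ~300 / ~1000 with the two larger cells overlapping
  a <- matrix(FALSE, 80, 80); a[5:11, 5:11] <- TRUE
  b <- rasteriseEllipse(c(80L, 80L), c(40, 36), 10, 9.6)
  c3 <- rasteriseEllipse(c(80L, 80L), c(40, 58), 18, 17.7)
  fr <- AnnotatedFrame(list(a, b, c3), 1:3)
  expect_gt(sum(b & c3), 0)
  spec <- optimizeSizeBoundaries(list(fr), nQuantiles = 25L)
  expect_gt(spec@boundaries[2L], sum(b))
  expect_lte(spec@boundaries[2L], sum(c3))
  expect_equal(budwatch:::withinCategoryOverlap(list(fr), spec@boundaries), 0)
})

test_that("identical areas fall back to default boundaries", {
  m1 <- matrix(FALSE, 30, 30); m1[2:6, 2:6] <- TRUE
  m2 <- matrix(FALSE, 30, 30); m2[20:24, 20:24] <- TRUE
  spec <- optimizeSizeBoundaries(list(AnnotatedFrame(list(m1, m2), 1:2)))
  expect_s4_class(spec, "SizeCategorySpec")
  expect_true(diff(spec@boundaries) > 0)
})

test_that("disc erosion follows the closed form: 21 px disc, depth 2 -> 17 px disc", {
  d21 <- discMask(10)                     # diameter 21
  spec <- SizeCategorySpec(c(1e5, 2e5), erosionDepth = c(2, 2, 2))
  ie <- makeInteriorEdgeTargets(AnnotatedFrame(list(d21), 1L), spec)
  eroded <- ie$interior_S > 0
  # closed form: the continuum erosion is the diameter-17 disc; allow the
  # lattice to differ by a boundary ring's worth of pixels
  expect_lt(abs(sum(eroded) - sum(discMask(8))) / sum(discMask(8)), 0.12)
  expect_true(all(d21[eroded]))                     # eroded subset original
})

test_that("erosion eases off until minSeedArea pixels survive", {
  tiny <- matrix(FALSE, 20, 20); tiny[9:11, 9:11] <- TRUE   # 9 px
  spec <- SizeCategorySpec(c(1e5, 2e5), erosionDepth = c(3, 3, 3),
                           minSeedArea = 5)
  ie <- makeInteriorEdgeTargets(AnnotatedFrame(list(tiny), 1L), spec)
  expect_gte(sum(ie$interior_S), 5)
  expect_true(all(tiny[ie$interior_S > 0]))
})

test_that("same-category cells overlapping by a thin strip erode apart", {
  a <- rasteriseEllipse(c(60L, 60L), c(30, 22), 10, 10)
  b <- rasteriseEllipse(c(60L, 60L), c(30, 40), 10, 10)   # 3 px strip overlap
  expect_gt(sum(a & b), 0)
  spec <- SizeCategorySpec(c(1e5, 2e5), erosionDepth = c(2, 2, 2))
  ie <- makeInteriorEdgeTargets(AnnotatedFrame(list(a, b), 1:2), spec)
  lab <- budwatch:::labelComponents(ie$interior_S > 0)
  expect_equal(max(lab), 2)
})

test_that("overlap channel is exactly the union of pairwise intersections", {
  # two squares sharing a 5x5 region
  a <- matrix(FALSE, 30, 30); a[5:14, 5:14] <- TRUE
  b <- matrix(FALSE, 30, 30); b[10:19, 10:19] <- TRUE
  ov <- makeOverlapTarget(AnnotatedFrame(list(a, b), 1:2))
  expect_equal(sum(ov), 25)
  expect_true(all(ov[10:14, 10:14] == 1))
  # disjoint cells give a zero map
  d <- matrix(FALSE, 30, 30); d[25:28, 25:28] <- TRUE
  expect_equal(sum(makeOverlapTarget(AnnotatedFrame(list(a, d), 1:2))), 0)
  # three cells sharing one pixel: union semantics, the pixel counts once
  c1 <- matrix(FALSE, 9, 9); c1[1:5, 5] <- TRUE
  c2 <- matrix(FALSE, 9, 9); c2[5, 1:5] <- TRUE
  c3 <- matrix(FALSE, 9, 9); c3[5:9, 5] <- TRUE
  ov3 <- makeOverlapTarget(AnnotatedFrame(list(c1, c2, c3), 1:3))
  expect_equal(sum(ov3), 1)
  expect_equal(ov3[5, 5], 1)
})

test_that("bud-neck channel marks the mother-bud interface", {
  mv <- fixtureMovie()
  fr <- Find(function(f) nrow(motherPairs(f)) > 0, frames(mv))
  bn <- makeBudneckTarget(fr)
  expect_gt(sum(bn), 0)
  lb <- trackLabels(fr)
  mp <- motherPairs(fr)
  # every neck pixel is within 3 px of both masks of some pair
  ok <- matrix(FALSE, nrow(bn), ncol(bn))
  for (r in seq_len(nrow(mp))) {
    db <- budwatch:::distanceToMask(masks(fr)[[match(mp[r, 1L], lb)]])
    dm <- budwatch:::distanceToMask(masks(fr)[[match(mp[r, 2L], lb)]])
    ok <- ok | (db <= 3 & dm <= 3)
  }
  expect_true(all(ok[bn > 0]))
  # no pairs -> zero map
  fr0 <- AnnotatedFrame(masks(fr), lb)
  expect_equal(sum(makeBudneckTarget(fr0)), 0)
  # a pair referencing a missing label errors
  expect_error(makeBudneckTarget(
    AnnotatedFrame(masks(fr)[1], lb[1],
                   motherPairs = cbind(bud = lb[1], mother = lb[1] + 99L),
                   dim = frameDim(fr))), "missing label")
})

test_that("target stack: channel order, category uniqueness, containment", {
  mv <- fixtureMovie()
  spec <- fixtureSpec()
  for (t in c(3L, 12L, 20L)) {
    fr <- frames(mv)[[t]]
    ts <- buildTargetStack(fr, spec)
    ch <- channels(ts)
    expect_identical(dimnames(ch)[[3L]], semanticChannelNames())
    allMasks <- Reduce(`|`, masks(fr))
    # overlap channel within the union of masks
    expect_true(all(allMasks[ch[, , "overlap"] > 0]))
    depths <- setNames(spec@erosionDepth, c("S", "M", "L"))
    for (i in seq_along(masks(fr))) {
      m <- masks(fr)[[i]]
      cat <- assignSizeCategory(m, spec)
      er <- budwatch:::erodeWithGuard(m, depths[[cat]], spec@minSeedArea)
      # eroded cell appears in exactly its category's interior channel
      hits <- vapply(c("S", "M", "L"), function(cc)
        all(ch[, , paste0("interior_", cc)][er] == 1), logical(1))
      expect_true(hits[[cat]])
      # edge pixels never intersect the same cell's eroded interior
      edge <- budwatch:::maskBoundary(m)
      expect_equal(sum(edge & er), 0)
      expect_true(all(m[er]))                       # erode(mask) within mask
      expect_true(all(ch[, , paste0("edge_", cat)][edge] == 1))
    }
  }
})

test_that("empty frame yields eight zero channels", {
  ts <- buildTargetStack(AnnotatedFrame(dim = c(32L, 32L)), fixtureSpec())
  expect_equal(sum(channels(ts)), 0)
  expect_equal(dim(channels(ts)), c(32L, 32L, 8L))
})

test_that("optimised boundaries do not exceed naive terciles in within-category overlap", {
  mv <- fixtureMovie()
  frs <- frames(mv)
  areas <- budwatch:::cellAreas(frs)
  terc <- quantile(areas, c(1, 2) / 3, names = FALSE)
  if (terc[2L] <= terc[1L]) terc[2L] <- terc[1L] + 1
  opt <- fixtureSpec()
  expect_lte(budwatch:::withinCategoryOverlap(frs, opt@boundaries),
             budwatch:::withinCategoryOverlap(frs, terc))
})
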