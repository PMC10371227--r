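# Multi-target semantic maps from annotated (possibly overlapping) masks:
# size-stratified eroded interiors and edges, pairwise overlaps, bud necks.

#' Assign a mask to a size category
#'
#' Categories are defined on the full (un-eroded) mask area with half-open
#' intervals: S = [0, b1), M = [b1, b2), L = [b2, Inf).
#'
#' @param mask logical matrix (non-empty), or a scalar area in px^2.
#' @param spec a [SizeCategorySpec-class].
#' @return "S", "M" or "L".
#' @export
assignSizeCategory <- function(mask, spec) {
  area <- if (is.matrix(mask)) sum(mask != 0) else mask
  if (area < 1) stop("empty mask has no size category")
  b <- spec@boundaries
  if (area < b[1L]) "S" else if (area < b[2L]) "M" else "L"
}

cellAreas <- function(frames) {
  unlist(lapply(frames, function(fr)
    vapply(masks(fr), function(m) sum(m != 0), numeric(1))))
}

withinCategoryOverlap <- function(frames, boundaries) {
  spec <- SizeCategorySpec(boundaries)
  total <- 0
  for (fr in frames) {
    mk <- masks(fr)
    if (length(mk) < 2L) next
    cat <- vapply(mk, assignSizeCategory, character(1), spec = spec)
    for (i in seq_len(length(mk) - 1L)) for (j in (i + 1L):length(mk)) {
      if (cat[i] != cat[j]) next
      total <- total + sum(mk[[i]] & mk[[j]])
    }
  }
  total
}

#' Choose size-category boundaries that minimise within-category overlap
#'
#' Grid search over area-quantile candidates for the two thresholds,
#' minimising the total pairwise overlap area between cells that fall in the
#' same category. Ties are broken by closeness to the area terciles, so with
#' no overlaps anywhere the terciles are returned. Deterministic given the
#' input.
#'
#' @param frames list of [AnnotatedFrame-class].
#' @param nCategories must be 3.
#' @param nQuantiles number of candidate quantiles per threshold.
#' @param erosionDepth,minSeedArea passed through to the returned spec.
#' @return A [SizeCategorySpec-class].
#' @export
optimizeSizeBoundaries <- function(frames, nCategories = 3L,
                                   nQuantiles = 12L,
                                   erosionDepth = c(1, 2, 3),
                                   minSeedArea = 5) {
  stopifnot(nCategories == 3L)
  areas <- cellAreas(frames)
  if (length(areas) < 2L) stop("need at least two cells to set boundaries")
  terc <- quantile(areas, c(1, 2) / 3, names = FALSE, type = 7)
  if (diff(range(areas)) == 0) {
    # all areas identical: no boundary can separate anything
    b <- c(areas[1L] + 1, areas[1L] + 2)
    return(SizeCategorySpec(b, erosionDepth, minSeedArea))
  }
  cand <- unique(quantile(areas, seq(0.05, 0.95, length.out = nQuantiles),
                          names = FALSE, type = 7))
  # midpoints between distinct areas separate better than the areas themselves
  cand <- sort(unique(c(cand, terc)))
  best <- NULL; bestObj <- Inf; bestTie <- Inf
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (cand[j] <= cand[i]) next
    b <- c(cand[i], cand[j])
    obj <- withinCategoryOverlap(frames, b)
    tie <- sum(abs(b - terc))
    if (obj < bestObj || (obj == bestObj && tie < bestTie)) {
      best <- b; bestObj <- obj; bestTie <- tie
    }
  }
  if (identical(terc[1], terc[2]) || is.null(best))
    best <- c(terc[1], terc[1] + 1)
  SizeCategorySpec(best, erosionDepth, minSeedArea)
}

# Erode one cell by its category depth, easing off stepwise (in 0.5 px
# steps) until at least minSeedArea pixels survive. For any positive depth
# the 8-connected outline is removed as well: a Euclidean erosion of depth
# 1 keeps diagonally-exposed boundary pixels (at distance sqrt(2)), which
# would let interior and edge targets intersect.
erodeWithGuard <- function(mask, depth, minSeedArea) {
  d <- depth
  repeat {
    er <- erodeDisc(mask, d)
    if (d >= 1) er <- er & !maskBoundary(mask)
    if (sum(er) >= minSeedArea || d <= 0) return(er)
    d <- d - 0.5
  }
}

#' Size-stratified interior and edge targets
#'
#' Per category: the interior channel is the union of member cells eroded by
#' that category's disc depth (eased per cell until `minSeedArea` pixels
#' survive); the edge channel is the union of member cells' un-eroded
#' boundary pixels (mask pixels 8-adjacent to background).
#'
#' @param frame an [AnnotatedFrame-class].
#' @param spec a [SizeCategorySpec-class].
#' @return list of six H x W binary matrices:
#'   interior_S/M/L then edge_S/M/L.
#' @export
makeInteriorEdgeTargets <- function(frame, spec) {
  d <- frameDim(frame)
  out <- replicate(6L, matrix(0, d[1L], d[2L]), simplify = FALSE)
  names(out) <- semanticChannelNames()[1:6]
  depths <- setNames(spec@erosionDepth, c("S", "M", "L"))
  for (m in masks(frame)) {
    cat <- assignSizeCategory(m, spec)
    er <- erodeWithGuard(m, depths[[cat]], spec@minSeedArea)
    ic <- paste0("interior_", cat); ec <- paste0("edge_", cat)
    out[[ic]] <- pmax(out[[ic]], er * 1)
    out[[ec]] <- pmax(out[[ec]], maskBoundary(m) * 1)
  }
  out
}

#' Pairwise-overlap target
#'
#' Union over all unordered cell pairs of their mask intersections,
#' irrespective of size category.
#'
#' @param frame an [AnnotatedFrame-class].
#' @return binary H x W matrix.
#' @export
makeOverlapTarget <- function(frame) {
  d <- frameDim(frame)
  out <- matrix(0, d[1L], d[2L])
  mk <- masks(frame)
  if (length(mk) >= 2L)
    for (i in seq_len(length(mk) - 1L)) for (j in (i + 1L):length(mk))
      out <- pmax(out, (mk[[i]] & mk[[j]]) * 1)
  out
}

#' Bud-neck target
#'
#' For each (bud, mother) pair the neck is the band of pixels within 1.5 px
#' of both masks (a ~3 px band straddling the mother-bud interface); the
#' channel is the union over pairs.
#'
#' @param frame an [AnnotatedFrame-class] with mother-bud pairs.
#' @return binary H x W matrix (all zero when there are no pairs).
#' @export
makeBudneckTarget <- function(frame) {
  d <- frameDim(frame)
  out <- matrix(0, d[1L], d[2L])
  mp <- motherPairs(frame)
  if (!nrow(mp)) return(out)
  lb <- trackLabels(frame)
  for (r in seq_len(nrow(mp))) {
    bi <- match(mp[r, 1L], lb); mi <- match(mp[r, 2L], lb)
    if (is.na(bi) || is.na(mi)) stop("mother-bud pair references missing label")
    neck <- (distanceToMask(masks(frame)[[bi]]) <= 1.5) &
      (distanceToMask(masks(frame)[[mi]]) <= 1.5)
    out <- pmax(out, neck * 1)
  }
  out
}

#' Build the full eight-channel semantic target stack
#'
#' Fixed channel order: interior_S, interior_M, interior_L, edge_S, edge_M,
#' edge_L, overlap, budneck.
#'
#' @param frame an [AnnotatedFrame-class].
#' @param spec a [SizeCategorySpec-class].
#' @return A binary [SemanticTargets-class].
#' @export
buildTargetStack <- function(frame, spec) {
  d <- frameDim(frame)
  ch <- array(0, dim = c(d[1L], d[2L], 8L))
  ie <- makeInteriorEdgeTargets(frame, spec)
  for (i in 1:6) ch[, , i] <- ie[[i]]
  ch[, , 7L] <- makeOverlapTarget(frame)
  ch[, , 8L] <- makeBudneckTarget(frame)
  SemanticTargets(ch, binary = TRUE)
}
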