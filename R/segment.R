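# Recovering individual, possibly overlapping cells from the eight-channel
# semantic maps: seeds from thresholded interiors, reversal of the training
# erosion, radial-spline refinement against the edge channels, and
# cross-category de-duplication.

raysForCategory <- c(S = 4L, M = 6L, L = 8L)

#' Extract seeds from the interior probability channels
#'
#' Each interior channel is thresholded at `pInterior`; 4-connected
#' components with at least `minSeedArea` pixels become seeds tagged with
#' that channel's size category.
#'
#' @param targets a [SemanticTargets-class] (probabilities or binary).
#' @param pInterior probability threshold.
#' @param minSeedArea minimum component area in px^2 (defaults to the
#'   category spec default, 5).
#' @return list of `list(mask, category)`; empty list when nothing seeds.
#' @export
extractSeeds <- function(targets, pInterior = 0.5, minSeedArea = 5) {
  out <- list()
  for (cat in c("S", "M", "L")) {
    ch <- semanticChannel(targets, paste0("interior_", cat))
    lab <- labelComponents(ch >= pInterior)
    if (max(lab) == 0) next
    for (k in seq_len(max(lab))) {
      m <- lab == k
      if (sum(m) >= minSeedArea)
        out[[length(out) + 1L]] <- list(mask = m, category = cat)
    }
  }
  out
}

#' Reverse the training erosion of a seed
#'
#' Dilates the seed by the same Euclidean disc depth that was used to erode
#' that size category's training masks.
#'
#' Target erosion always removes the 8-connected outline in addition to the
#' Euclidean disc, so for nominal depths below sqrt(2) the outline removal
#' dominates and the effective erosion radius is about 1.7 px; the reversal
#' dilates by that effective depth.
#'
#' @param seed logical matrix (a seed from [extractSeeds()]).
#' @param category "S", "M" or "L".
#' @param spec the [SizeCategorySpec-class] whose depths were used.
#' @return logical matrix (the grown mask).
#' @export
reverseErosion <- function(seed, category, spec) {
  depth <- spec@erosionDepth[match(category, c("S", "M", "L"))]
  if (depth >= 1) depth <- max(depth, 1.7)
  dilateDisc(seed, depth)
}

splineRadius <- function(spl, theta) {
  ang <- spl@knotAngles; rad <- spl@knotRadii
  a0 <- ang[1L]
  th <- (theta - a0) %% (2 * pi) + a0
  if (length(ang) < 3L) {
    # too few knots for a periodic spline: linear interpolation in angle
    xx <- c(ang, ang[1L] + 2 * pi); yy <- c(rad, rad[1L])
    return(stats::approx(xx, yy, xout = th)$y)
  }
  stats::spline(c(ang, ang[1L] + 2 * pi), c(rad, rad[1L]),
                method = "periodic", xout = th)$y
}

#' Rasterise a radial spline into a binary mask
#' @param spl a [RadialSpline-class].
#' @param dimHW output (H, W).
#' @return logical matrix; star-convex about the spline centre.
#' @export
rasteriseSpline <- function(spl, dimHW) {
  h <- dimHW[1L]; w <- dimHW[2L]
  out <- matrix(FALSE, h, w)
  rmax <- max(spl@knotRadii) * 1.3 + 2
  rows <- max(1L, floor(spl@centre[1L] - rmax)):
    min(h, ceiling(spl@centre[1L] + rmax))
  cols <- max(1L, floor(spl@centre[2L] - rmax)):
    min(w, ceiling(spl@centre[2L] + rmax))
  if (!length(rows) || !length(cols)) return(out)
  dy <- matrix(rows - spl@centre[1L], length(rows), length(cols))
  dx <- matrix(cols - spl@centre[2L], length(rows), length(cols),
               byrow = TRUE)
  rho <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  rOf <- splineRadius(spl, as.numeric(theta))
  out[rows, cols] <- rho <= pmax(rOf, 0)
  out
}

#' Fit a radial spline to a grown mask using the edge evidence
#'
#' Candidate edge pixels are the positive pixels of the category's edge
#' channel, weighted by their edge probability, down-weighted by a Gaussian
#' (sd `sigmaW`) in their distance from the grown mask's own boundary, and
#' up-weighted (x `overlapBoost`) inside the overlap channel, where cell
#' boundaries cross other cells. Each of the `nRays` equally spaced rays
#' contributes one knot: a local (Gaussian-in-angle) weighted linear
#' regression of candidate radius on angle, evaluated at the ray. Because
#' edge pixels lie inside the mask, about half a pixel inside the continuum
#' boundary, half a pixel is added to each estimated knot. A ray with no
#' candidates falls back to the grown mask's own boundary radius.
#'
#' @param grown logical matrix (from [reverseErosion()]).
#' @param edgeChannel numeric matrix: the edge channel of the seed's
#'   category.
#' @param overlapChannel numeric matrix (the overlap channel), or NULL.
#' @param nRays number of rays (4, 6 or 8; tied to size category).
#' @param sigmaW Gaussian distance weighting sd in px.
#' @param overlapBoost multiplicative up-weight inside the overlap channel.
#' @return A [RadialSpline-class].
#' @export
fitRadialSpline <- function(grown, edgeChannel, overlapChannel = NULL,
                            nRays = 6L, sigmaW = 3, overlapBoost = 2) {
  stopifnot(any(grown))
  idx <- which(grown, arr.ind = TRUE)
  centre <- c(mean(idx[, 1L]), mean(idx[, 2L]))
  bnd <- maskBoundary(grown)
  bidx <- which(bnd, arr.ind = TRUE)
  bAng <- atan2(bidx[, 1L] - centre[1L], bidx[, 2L] - centre[2L]) %% (2 * pi)
  bRad <- sqrt((bidx[, 1L] - centre[1L])^2 + (bidx[, 2L] - centre[2L])^2)
  distBnd <- distanceToMask(bnd)
  cand <- which(edgeChannel > 0.1 & distBnd <= 3 * sigmaW, arr.ind = TRUE)
  w <- numeric(0); cAng <- numeric(0); cRad <- numeric(0)
  if (nrow(cand)) {
    ii <- cand[, 1L] + (cand[, 2L] - 1L) * nrow(grown)
    w <- edgeChannel[ii] * exp(-distBnd[ii]^2 / (2 * sigmaW^2))
    if (!is.null(overlapChannel))
      w <- w * ifelse(overlapChannel[ii] > 0.5, overlapBoost, 1)
    cAng <- atan2(cand[, 1L] - centre[1L],
                  cand[, 2L] - centre[2L]) %% (2 * pi)
    cRad <- sqrt((cand[, 1L] - centre[1L])^2 + (cand[, 2L] - centre[2L])^2)
  }
  rayAng <- 2 * pi * (seq_len(nRays) - 1L) / nRays
  half <- pi / nRays
  sigA <- half / 1.2
  knots <- vapply(rayAng, function(a) {
    dd <- ((cAng - a + pi) %% (2 * pi)) - pi
    ww <- w * exp(-dd^2 / (2 * sigA^2))
    sel <- which(abs(dd) <= 2 * half & ww > 1e-8)
    if (length(sel) >= 3L) {
      X <- cbind(1, dd[sel]); Wg <- ww[sel]
      beta <- tryCatch(solve(crossprod(X, X * Wg),
                             crossprod(X, Wg * cRad[sel])),
                       error = function(e) NULL)
      if (!is.null(beta)) return(beta[1L] + 0.5)
    }
    if (length(sel)) return(sum(cRad[sel] * ww[sel]) / sum(ww[sel]) + 0.5)
    dd <- abs(((bAng - a + pi) %% (2 * pi)) - pi)
    sel <- which(dd <= half)
    if (length(sel)) return(median(bRad[sel]) + 0.5)
    if (length(bRad)) median(bRad) + 0.5 else 1
  }, numeric(1))
  new("RadialSpline", centre = centre, knotAngles = rayAng,
      knotRadii = pmax(knots, 0.5))
}

#' Drop near-duplicate instances across size categories
#'
#' A cell near a category boundary can seed in two interior channels.
#' Instances are kept greedily by decreasing score; any instance whose mask
#' IoU with an already-kept instance exceeds `iouCutoff` is dropped. True
#' mother-bud overlaps are far below the cutoff, so genuinely overlapping
#' cells are both kept.
#'
#' @param instances list of [SegmentedInstance-class].
#' @param iouCutoff IoU above which two instances are deemed duplicates.
#' @return Filtered list, ordered by decreasing score.
#' @export
resolveDuplicates <- function(instances, iouCutoff = 0.5) {
  if (length(instances) <= 1L) return(instances)
  ord <- order(vapply(instances, instanceScore, numeric(1)),
               decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    dup <- any(vapply(kept, function(k)
      maskIoU(instanceMask(k), instanceMask(instances[[i]])) > iouCutoff,
      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- instances[[i]]
  }
  kept
}

# Radial disagreement between the fitted knots and the grown mask's own
# boundary, in px (mean over rays).
splineDisagreement <- function(spl, grown) {
  bnd <- which(maskBoundary(grown), arr.ind = TRUE)
  bAng <- atan2(bnd[, 1L] - spl@centre[1L],
                bnd[, 2L] - spl@centre[2L]) %% (2 * pi)
  bRad <- sqrt((bnd[, 1L] - spl@centre[1L])^2 +
                 (bnd[, 2L] - spl@centre[2L])^2)
  half <- pi / length(spl@knotAngles)
  d <- vapply(seq_along(spl@knotAngles), function(k) {
    dd <- abs(((bAng - spl@knotAngles[k] + pi) %% (2 * pi)) - pi)
    sel <- dd <= half
    if (!any(sel)) return(0)
    abs(spl@knotRadii[k] - 0.5 - median(bRad[sel]))
  }, numeric(1))
  mean(d)
}

#' Segment one frame's semantic maps into cell instances
#'
#' Composition of [extractSeeds()], [reverseErosion()], [fitRadialSpline()]
#' (with 4/6/8 rays for S/M/L) and [resolveDuplicates()]. The fitted spline
#' always parameterises the exported outline; the instance mask adopts the
#' rasterised spline only when the edge evidence disagrees with the grown
#' mask by more than `trustPx` per ray on average — a low-order spline
#' discards pixel-level detail, so sub-pixel disagreement is no reason to
#' redraw an already-confirmed boundary. Returned instances may overlap one
#' another: overlap between a mother and its bud is expected and preserved.
#'
#' @param targets a [SemanticTargets-class] (probabilities).
#' @param spec the [SizeCategorySpec-class] used for the targets.
#' @param pInterior seed threshold.
#' @param sigmaW,overlapBoost spline re-weighting parameters.
#' @param iouCutoff duplicate cutoff.
#' @param trustPx mean radial disagreement (px) above which the spline
#'   mask replaces the grown mask.
#' @return list of [SegmentedInstance-class].
#' @export
segmentFrame <- function(targets, spec, pInterior = 0.5, sigmaW = 3,
                         overlapBoost = 2, iouCutoff = 0.5, trustPx = 1) {
  seeds <- extractSeeds(targets, pInterior, spec@minSeedArea)
  if (!length(seeds)) return(list())
  ov <- semanticChannel(targets, "overlap")
  out <- list()
  for (sd in seeds) {
    grown <- reverseErosion(sd$mask, sd$category, spec)
    edge <- semanticChannel(targets, paste0("edge_", sd$category))
    spl <- fitRadialSpline(grown, edge, ov,
                           nRays = raysForCategory[[sd$category]],
                           sigmaW = sigmaW, overlapBoost = overlapBoost)
    mask <- if (splineDisagreement(spl, grown) > trustPx)
      rasteriseSpline(spl, dim(grown)) else grown
    if (!any(mask)) next
    interior <- semanticChannel(targets, paste0("interior_", sd$category))
    score <- min(max(mean(interior[mask]), 0), 1)
    out[[length(out) + 1L]] <- new("SegmentedInstance", spline = spl,
                                   mask = mask, category = sd$category,
                                   score = score)
  }
  resolveDuplicates(out, iouCutoff)
}
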