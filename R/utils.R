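# Low-level binary-mask morphology and geometry helpers.
#
# Erosion and dilation use the exact Euclidean disc via distance maps, so
# reverse_erosion is the exact inverse operation on convex shapes (up to
# rasterisation): erode keeps pixels further than `depth` from background,
# dilate adds background pixels within `depth` of the mask.

asMaskMatrix <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  m
}

#' Erode a mask by a Euclidean disc
#' @param mask logical matrix.
#' @param depth disc radius in px (0 = identity).
#' @return logical matrix, subset of `mask`.
#' @export
erodeDisc <- function(mask, depth) {
  if (depth <= 0) return(mask != 0)
  dm <- asMaskMatrix(EBImage::distmap(matrix(as.numeric(mask != 0),
                                             nrow(mask))))
  dm > depth
}

#' Dilate a mask by a Euclidean disc
#' @param mask logical matrix.
#' @param depth disc radius in px (0 = identity).
#' @return logical matrix, superset of `mask`.
#' @export
dilateDisc <- function(mask, depth) {
  mask <- mask != 0
  if (depth <= 0) return(mask)
  if (all(mask) || !any(mask)) return(mask)
  dm <- asMaskMatrix(EBImage::distmap(matrix(as.numeric(!mask), nrow(mask))))
  mask | (dm <= depth)
}

# Mask pixels 8-adjacent to background (outline kept inside the mask).
maskBoundary <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    inner <- inner & pad[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  }
  mask & !inner
}

# 4-connected component labelling (EBImage::bwlabel is 4-connected).
labelComponents <- function(mask) {
  asMaskMatrix(EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask))))
}

# Euclidean distance of every pixel to the nearest mask pixel (0 on the mask).
distanceToMask <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  out <- matrix(0, nrow(mask), ncol(mask))
  dm <- asMaskMatrix(EBImage::distmap(matrix(as.numeric(!mask), nrow(mask))))
  out[!mask] <- dm[!mask]
  out
}

# Rasterise an ellipse (centre (row, col), semi-axes a >= b, orientation theta
# measured from the column axis) into a logical H x W matrix.
rasteriseEllipse <- function(dimHW, centre, a, b, theta = 0) {
  h <- dimHW[1L]; w <- dimHW[2L]
  out <- matrix(FALSE, h, w)
  r0 <- centre[1L]; c0 <- centre[2L]
  rr <- max(a, b)
  rows <- max(1L, floor(r0 - rr)):min(h, ceiling(r0 + rr))
  cols <- max(1L, floor(c0 - rr)):min(w, ceiling(c0 + rr))
  if (!length(rows) || !length(cols)) return(out)
  dy <- matrix(rows - r0, length(rows), length(cols))
  dx <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  out[rows, cols] <- u * u + v * v <= 1
  out
}

# Area of intersection of two discs with radii R, r and centre distance d.
lensArea <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(pi * min(R, r)^2)
  r1 <- max(R, r); r2 <- min(R, r)
  d1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  d2 <- d - d1
  a1 <- r1^2 * acos(pmin(pmax(d1 / r1, -1), 1)) - d1 * sqrt(max(r1^2 - d1^2, 0))
  a2 <- r2^2 * acos(pmin(pmax(d2 / r2, -1), 1)) - d2 * sqrt(max(r2^2 - d2^2, 0))
  a1 + a2
}

# Centre distance giving a bud (radius r) the requested overlap fraction of
# its own area with a mother of radius R.
budCentreDistance <- function(R, r, frac) {
  target <- frac * pi * r^2
  lo <- abs(R - r) + 1e-9; hi <- R + r - 1e-9
  if (lensArea(R, r, hi) >= target) return(hi)
  if (lensArea(R, r, lo) <= target) return(lo)
  stats::uniroot(function(d) lensArea(R, r, d) - target, c(lo, hi),
                 tol = 1e-6)$root
}

weightedMedian <- function(x, w) {
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Minimum-cost assignment of rows to columns of a finite cost matrix,
#' rectangular matrices padded internally. O(n^3) shortest augmenting paths.
#'
#' @param cost numeric matrix; use large values to discourage pairs.
#' @return Integer vector of length `nrow(cost)`: assigned column per row
#'   (NA where a row is left unassigned because columns ran out).
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer())
  if (m == 0L) return(rep(NA_integer_, n))
  big <- max(abs(cost[is.finite(cost)]), 1) * 1e3
  cost[!is.finite(cost)] <- big
  k <- max(n, m)
  sq <- matrix(big, k, k)
  sq[seq_len(n), seq_len(m)] <- cost
  # shortest augmenting path with potentials; columns indexed 1..k, index
  # k+1 is the virtual start column
  u <- numeric(k + 1L); v <- numeric(k + 1L)
  p <- integer(k + 1L); way <- integer(k + 1L)
  for (i in seq_len(k)) {
    p[k + 1L] <- i
    j0 <- k + 1L
    minv <- rep(Inf, k + 1L)
    used <- rep(FALSE, k + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(k)) {
        if (used[j]) next
        cur <- sq[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      sel <- used
      u[p[sel]] <- u[p[sel]] + delta
      v[sel] <- v[sel] - delta
      minv[!sel] <- minv[!sel] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == k + 1L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in seq_len(k)) {
    i <- p[j]
    if (i >= 1L && i <= n && j <= m) assign[i] <- j
  }
  assign
}
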