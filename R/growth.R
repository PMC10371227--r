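# Conical volume estimation, Gaussian-process smoothing/differentiation of
# volume series, combined mother+bud growth rate, the cytokinesis-time
# heuristic and the real-time escape-fraction statistic.
#
# GP details: a stationary Matern-5/2 (or squared-exponential) kernel plus
# white noise; hyperparameters by marginal-likelihood maximisation with
# seeded restarts; the growth rate is the analytically differentiated
# posterior (mean and sd from the derivative covariance). No parametric
# growth law (bilinear/exponential) is assumed.

#' Conical volume of a 2-D mask
#'
#' Elevates every foreground pixel to a height equal to its Euclidean
#' distance to the background and integrates the two mirror-symmetric
#' halves: V = calibration * 2 * pixelSize^3 * sum(heights). For a disc of
#' radius r this converges to (2/3) pi r^3. The distance map is evaluated on
#' a `supersample`-times pixel-replicated mask (and rescaled accordingly):
#' the raw lattice distance to the nearest background site overshoots the
#' mask boundary by up to half a pixel, a bias of several percent for
#' bud-sized cells that the finer lattice largely removes.
#'
#' @param mask logical matrix, non-empty.
#' @param pixelSize um per pixel.
#' @param calibration multiplicative calibration factor (default 1).
#' @param supersample integer lattice refinement factor (default 2;
#'   1 = the raw distance map).
#' @return volume in um^3.
#' @export
conicalVolume <- function(mask, pixelSize, calibration = 1,
                          supersample = 2L) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask has no volume")
  s <- as.integer(supersample)
  ms <- mask[rep(seq_len(nrow(mask)), each = s),
             rep(seq_len(ncol(mask)), each = s), drop = FALSE]
  dm <- asMaskMatrix(EBImage::distmap(matrix(as.numeric(ms), nrow(ms))))
  calibration * 2 * pixelSize^3 * sum(dm) / s^3
}

# Matern-5/2 kernel and the derivatives needed for the rate posterior.
# t = x - x'; a = sqrt(5)/ell.
matern52 <- function(t, sf2, ell) {
  a <- sqrt(5) / ell; u <- abs(t)
  sf2 * (1 + a * u + a^2 * u^2 / 3) * exp(-a * u)
}
matern52_d1 <- function(t, sf2, ell) {          # d k / d t
  a <- sqrt(5) / ell; u <- abs(t)
  -sf2 * (a^2 * t / 3) * (1 + a * u) * exp(-a * u)
}
matern52_d11 <- function(t, sf2, ell) {         # cov(f'(x), f'(x')) = -k''
  a <- sqrt(5) / ell; u <- abs(t)
  sf2 * (a^2 / 3) * (1 + a * u - a^2 * u^2) * exp(-a * u)
}
rbfK <- function(t, sf2, ell) sf2 * exp(-t^2 / (2 * ell^2))
rbf_d1 <- function(t, sf2, ell) -t / ell^2 * rbfK(t, sf2, ell)
rbf_d11 <- function(t, sf2, ell) (1 / ell^2 - t^2 / ell^4) * rbfK(t, sf2, ell)

gpNegLogLik <- function(theta, tt, y, kern) {
  sf2 <- exp(theta[1L]); ell <- exp(theta[2L]); sn2 <- exp(theta[3L])
  D <- outer(tt, tt, "-")
  K <- kern(D, sf2, ell) + diag(sn2, length(tt))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))) +
               0.5 * length(y) * log(2 * pi))
}

#' Smooth a volume series and estimate its derivative with a GP
#'
#' Fits a zero-mean GP (after centring) with a stationary kernel plus white
#' noise to the present (non-missing) volumes, maximising the marginal
#' likelihood from several seeded restarts, and returns the posterior mean
#' and sd of both the volume and its time derivative at the observed times.
#' Times are in minutes; rates are reported in um^3/h.
#'
#' @param series a [VolumeSeries-class] with at least 4 present points.
#' @param kernel "matern52" (default) or "rbf".
#' @param nRestarts optimisation restarts.
#' @param seed seed for the restart draws.
#' @return A [GrowthEstimate-class].
#' @export
fitGPVolume <- function(series, kernel = c("matern52", "rbf"),
                        nRestarts = 3L, seed = 1L) {
  kernel <- match.arg(kernel)
  ok <- !series@missing & is.finite(series@volumes)
  tt <- series@times[ok] / 60       # hours, so rates are um^3/h
  y0 <- series@volumes[ok]
  if (length(tt) < 4L) stop("need at least 4 present time points")
  if (any(!is.finite(y0))) stop("non-finite volumes")
  mu <- mean(y0); y <- y0 - mu
  vy <- max(var(y), 1e-6)
  dtMin <- min(diff(tt)); span <- diff(range(tt))
  kern <- if (kernel == "matern52") matern52 else rbfK
  kd1 <- if (kernel == "matern52") matern52_d1 else rbf_d1
  kd11 <- if (kernel == "matern52") matern52_d11 else rbf_d11
  lower <- c(log(vy * 1e-3), log(dtMin), log(vy * 1e-3))
  upper <- c(log(vy * 1e3), log(span), log(vy))
  set.seed(seed)
  starts <- rbind(
    c(log(vy), log(span / 3), log(vy * 0.05)),
    matrix(runif(3 * max(nRestarts - 1L, 0L), lower, upper), ncol = 3L,
           byrow = TRUE))
  best <- NULL; bestVal <- Inf
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(pmin(pmax(starts[r, ], lower), upper), gpNegLogLik,
            tt = tt, y = y, kern = kern, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < bestVal) {
      best <- fit$par; bestVal <- fit$value
    }
  }
  if (is.null(best)) stop("GP hyperparameter optimisation failed")
  sf2 <- exp(best[1L]); ell <- exp(best[2L]); sn2 <- exp(best[3L])
  D <- outer(tt, tt, "-")
  K <- kern(D, sf2, ell) + diag(sn2, length(tt))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  Ks <- kern(D, sf2, ell)               # test points = observed times
  volMean <- as.numeric(Ks %*% alpha) + mu
  Vs <- backsolve(ch, forwardsolve(t(ch), t(Ks)))
  volVar <- pmax(kern(0, sf2, ell) - colSums(Vs * t(Ks)), 0)
  Kd <- kd1(D, sf2, ell)                # cov(f'(t_i), f(t_j))
  rateMean <- as.numeric(Kd %*% alpha)
  Vd <- backsolve(ch, forwardsolve(t(ch), t(Kd)))
  rateVar <- pmax(kd11(0, sf2, ell) - colSums(Vd * t(Kd)), 0)
  new("GrowthEstimate", track = series@track, times = series@times[ok],
      volMean = volMean, volSD = sqrt(volVar), rateMean = rateMean,
      rateSD = sqrt(rateVar), hyper = c(signalVar = sf2, lengthScale = ell,
                                        noiseVar = sn2),
      kernel = kernel)
}

#' Combined mother + bud growth rate
#'
#' The growth rate of a cell is the rate of change of the total volume of
#' the mother and its current bud, i.e. the sum of their rates. Variances
#' add under the documented independence assumption.
#'
#' @param mother a [GrowthEstimate-class].
#' @param bud a [GrowthEstimate-class] or NULL (bud absent: the mother's
#'   rate is returned).
#' @return data.frame(time, rate, rate_sd) on the intersecting time grid.
#' @export
combinedGrowthRate <- function(mother, bud = NULL) {
  if (is.null(bud))
    return(data.frame(time = mother@times, rate = mother@rateMean,
                      rate_sd = mother@rateSD))
  shared <- intersect(mother@times, bud@times)
  if (!length(shared)) stop("mother and bud time ranges do not intersect")
  im <- match(shared, mother@times); ib <- match(shared, bud@times)
  data.frame(time = shared,
             rate = mother@rateMean[im] + bud@rateMean[ib],
             rate_sd = sqrt(mother@rateSD[im]^2 + bud@rateSD[ib]^2))
}

#' Cytokinesis time from the end of the peak in bud growth rate
#'
#' Finds the maximum of the bud's growth rate and returns the first later
#' time at which the rate has fallen to `alpha` times that maximum; if the
#' rate never falls below the threshold (e.g. monotonically increasing
#' series) the last time point is returned with `flagged = TRUE`.
#'
#' @param bud a [GrowthEstimate-class] for the bud.
#' @param alpha fraction of the peak rate defining its end.
#' @return list(index, time, flagged).
#' @export
estimateCytokinesis <- function(bud, alpha = 0.5) {
  r <- bud@rateMean
  imax <- which.max(r)
  thr <- alpha * r[imax]
  after <- which(seq_along(r) > imax & r <= thr)
  if (length(after))
    list(index = after[1L], time = bud@times[after[1L]], flagged = FALSE)
  else
    list(index = length(r), time = bud@times[length(r)], flagged = TRUE)
}

#' Fraction of mothers that have escaped a growth lag
#'
#' A mother has escaped by time t when at least one of its buds or
#' daughters has shown a growth rate above `threshold` at or before t.
#' The statistic is non-decreasing in time and non-increasing in the
#' threshold, and is the quantity a real-time controller consumes.
#'
#' @param budRates data.frame(mother, time, rate): growth-rate samples of
#'   buds/daughters keyed by their mother.
#' @param threshold growth-rate threshold in um^3/h (default 15).
#' @param times query times (default: the sorted unique sample times).
#' @return data.frame(time, fraction).
#' @export
escapeFraction <- function(budRates, threshold = 15, times = NULL) {
  mothers <- unique(budRates$mother)
  if (!length(mothers)) stop("no mother cells")
  if (is.null(times)) times <- sort(unique(budRates$time))
  exceed <- budRates[budRates$rate > threshold, , drop = FALSE]
  firstEsc <- tapply(exceed$time, exceed$mother, min)
  frac <- vapply(times, function(t)
    sum(!is.na(firstEsc) & firstEsc <= t) / length(mothers), numeric(1))
  data.frame(time = times, fraction = frac)
}
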