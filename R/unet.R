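# A small multi-target U-net implemented directly in R.
#
# Convolutions are 3x3 stride-1 pad-1, realised as im2col (nine shifted
# views) followed by a BLAS matrix product, so forward and backward passes
# are dense linear algebra. The network is deliberately tiny (base 8 filters,
# four resolution levels by default): it is meant for desk-scale experiments
# on synthetic data, with the oracle bypass (`oraclePredict`) available to
# test the downstream pipeline independently of training.
#
# Layout: activations are H x W x C arrays; the Z sections of a stack enter
# as input channels of a single 2-D network.

im2col3 <- function(A) {
  H <- dim(A)[1L]; W <- dim(A)[2L]; C <- dim(A)[3L]
  P <- matrix(0, H * W, 9L * C)
  pad <- array(0, c(H + 2L, W + 2L, C))
  pad[2:(H + 1L), 2:(W + 1L), ] <- A
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    P[, ((k - 1L) * C + 1L):(k * C)] <-
      pad[(2L + dy):(H + 1L + dy), (2L + dx):(W + 1L + dx), , drop = FALSE]
  }
  P
}

col2im3 <- function(dP, H, W, C) {
  pad <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    rows <- (2L + dy):(H + 1L + dy); cols <- (2L + dx):(W + 1L + dx)
    pad[rows, cols, ] <- pad[rows, cols, , drop = FALSE] +
      array(dP[, ((k - 1L) * C + 1L):(k * C)], c(H, W, C))
  }
  pad[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

convForward <- function(A, Wm, b) {
  H <- dim(A)[1L]; W <- dim(A)[2L]
  P <- im2col3(A)
  Z <- sweep(P %*% Wm, 2L, b, "+")
  list(out = array(Z, c(H, W, ncol(Wm))), P = P)
}

convBackward <- function(dOut, P, Wm, H, W, Cin) {
  dZ <- matrix(dOut, H * W, dim(dOut)[3L])
  list(dW = crossprod(P, dZ), db = colSums(dZ),
       dX = col2im3(dZ %*% t(Wm), H, W, Cin))
}

poolForward <- function(A) {
  H <- dim(A)[1L]; W <- dim(A)[2L]; C <- dim(A)[3L]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  q <- list(A[i1, j1, , drop = FALSE], A[i2, j1, , drop = FALSE],
            A[i1, j2, , drop = FALSE], A[i2, j2, , drop = FALSE])
  m <- pmax(q[[1L]], q[[2L]], q[[3L]], q[[4L]])
  arg <- array(0L, dim(m))
  for (k in 4:1) arg[q[[k]] == m] <- k   # ties go to the earliest quadrant
  list(out = m, arg = arg)
}

poolBackward <- function(dOut, arg, H, W) {
  C <- dim(dOut)[3L]
  dX <- array(0, c(H, W, C))
  i1 <- seq(1L, H, 2L); j1 <- seq(1L, W, 2L)
  sel <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    msk <- arg == k
    g <- dOut * msk
    dX[i1 + sel[[k]][1L], j1 + sel[[k]][2L], ] <-
      dX[i1 + sel[[k]][1L], j1 + sel[[k]][2L], ] + g
  }
  dX
}

upsample2 <- function(A) {
  A[rep(seq_len(dim(A)[1L]), each = 2L),
    rep(seq_len(dim(A)[2L]), each = 2L), , drop = FALSE]
}

downsum2 <- function(dOut) {
  H <- dim(dOut)[1L]; W <- dim(dOut)[2L]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  dOut[i1, j1, , drop = FALSE] + dOut[i2, j1, , drop = FALSE] +
    dOut[i1, j2, , drop = FALSE] + dOut[i2, j2, , drop = FALSE]
}

unetLayerSpec <- function(config) {
  D <- config@depth
  f <- config@baseFilters * 2L^(seq_len(D) - 1L)
  layers <- list()
  inc <- config@inSections
  for (i in seq_len(D)) {
    layers[[paste0("enc", i, "a")]] <- c(inc, f[i])
    layers[[paste0("enc", i, "b")]] <- c(f[i], f[i])
    inc <- f[i]
  }
  for (i in rev(seq_len(D - 1L))) {
    layers[[paste0("up", i)]] <- c(f[i + 1L], f[i])
    layers[[paste0("dec", i)]] <- c(2L * f[i], f[i])
    layers[[paste0("dec", i, "b")]] <- c(f[i], f[i])
  }
  layers[["head"]] <- c(f[1L], config@outChannels)
  layers
}

#' Build the small multi-target U-net
#'
#' Weights are He-initialised from the configured seed, so two models built
#' from equal configurations are identical.
#'
#' @param config a [UNetConfig-class].
#' @return A model handle (list of class `budwatchUNet`).
#' @export
buildUnet <- function(config) {
  validObject(config)
  set.seed(config@seed)
  spec <- unetLayerSpec(config)
  params <- list()
  for (nm in names(spec)) {
    cin <- spec[[nm]][1L]; cout <- spec[[nm]][2L]
    kk <- if (nm == "head") 1L else 9L
    params[[nm]] <- list(
      W = matrix(rnorm(kk * cin * cout, 0, sqrt(2 / (kk * cin))),
                 kk * cin, cout),
      b = numeric(cout))
  }
  structure(list(config = config, params = params, spec = spec,
                 adam = NULL, step = 0L),
            class = "budwatchUNet")
}

#' @export
print.budwatchUNet <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                   numeric(1)))
  cat(sprintf("budwatchUNet: depth %d, base %d, %d input section(s), %d parameters\n",
              x$config@depth, x$config@baseFilters, x$config@inSections,
              as.integer(np)))
  invisible(x)
}

padToMultiple <- function(A, mult, value = 0) {
  H <- dim(A)[1L]; W <- dim(A)[2L]
  H2 <- as.integer(ceiling(H / mult) * mult)
  W2 <- as.integer(ceiling(W / mult) * mult)
  if (H2 == H && W2 == W) return(list(A = A, H = H, W = W))
  out <- array(value, c(H2, W2, dim(A)[3L]))
  out[seq_len(H), seq_len(W), ] <- A
  list(A = out, H = H, W = W)
}

unetForward <- function(model, x, keepCache = FALSE) {
  cfg <- model$config; D <- cfg@depth; pr <- model$params
  cache <- list(x = x)
  enc <- list(); A <- x
  for (i in seq_len(D)) {
    for (s in c("a", "b")) {
      nm <- paste0("enc", i, s)
      cv <- convForward(A, pr[[nm]]$W, pr[[nm]]$b)
      if (keepCache) cache[[paste0("P_", nm)]] <- cv$P
      A <- cv$out; A[A < 0] <- 0
      if (keepCache) cache[[paste0("R_", nm)]] <- A > 0
    }
    enc[[i]] <- A
    if (i < D) {
      pl <- poolForward(A)
      if (keepCache) cache[[paste0("arg", i)]] <- pl$arg
      A <- pl$out
    }
  }
  for (i in rev(seq_len(D - 1L))) {
    up <- upsample2(A)
    nm <- paste0("up", i)
    cv <- convForward(up, pr[[nm]]$W, pr[[nm]]$b)
    if (keepCache) cache[[paste0("P_", nm)]] <- cv$P
    A <- cv$out; A[A < 0] <- 0
    if (keepCache) cache[[paste0("R_", nm)]] <- A > 0
    cat2 <- array(c(A, enc[[i]]), c(dim(A)[1L], dim(A)[2L],
                                    dim(A)[3L] + dim(enc[[i]])[3L]))
    for (nm in c(paste0("dec", i), paste0("dec", i, "b"))) {
      cv <- convForward(if (nm == paste0("dec", i)) cat2 else A,
                        pr[[nm]]$W, pr[[nm]]$b)
      if (keepCache) cache[[paste0("P_", nm)]] <- cv$P
      A <- cv$out; A[A < 0] <- 0
      if (keepCache) cache[[paste0("R_", nm)]] <- A > 0
    }
  }
  H <- dim(A)[1L]; W <- dim(A)[2L]
  Z <- matrix(A, H * W, dim(A)[3L]) %*% pr$head$W
  Z <- sweep(Z, 2L, pr$head$b, "+")
  if (keepCache) cache$headIn <- A
  prob <- array(1 / (1 + exp(-Z)), c(H, W, cfg@outChannels))
  list(prob = prob, cache = if (keepCache) cache else NULL)
}

unetBackward <- function(model, fw, target) {
  cfg <- model$config; D <- cfg@depth; pr <- model$params
  cache <- fw$cache
  H <- dim(fw$prob)[1L]; W <- dim(fw$prob)[2L]
  wc <- cfg@channelWeights
  pw <- cfg@posWeight
  # d(loss)/d(logit) for weighted per-channel binary cross-entropy with
  # positive-class weight pw (targets are sparse)
  dZ <- sweep((1 - target) * fw$prob + pw * target * (fw$prob - 1),
              3L, wc, "*") / (H * W)
  grads <- list()
  headIn <- cache$headIn
  dZm <- matrix(dZ, H * W, cfg@outChannels)
  grads$head <- list(
    dW = crossprod(matrix(headIn, H * W, dim(headIn)[3L]), dZm),
    db = colSums(dZm))
  dA <- array(dZm %*% t(pr$head$W), dim(headIn))
  enc_ch <- cfg@baseFilters * 2L^(seq_len(D) - 1L)
  dEnc <- vector("list", D)
  for (i in seq_len(D - 1L)) {
    nmB <- paste0("dec", i, "b")
    h <- dim(cache[[paste0("R_", nmB)]])[1L]
    w <- dim(cache[[paste0("R_", nmB)]])[2L]
    dA <- dA * cache[[paste0("R_", nmB)]]
    bk <- convBackward(dA, cache[[paste0("P_", nmB)]], pr[[nmB]]$W, h, w,
                       enc_ch[i])
    grads[[nmB]] <- list(dW = bk$dW, db = bk$db)
    dA <- bk$dX
    nm <- paste0("dec", i)
    dA <- dA * cache[[paste0("R_", nm)]]
    cin <- 2L * enc_ch[i]
    bk <- convBackward(dA, cache[[paste0("P_", nm)]], pr[[nm]]$W, h, w, cin)
    grads[[nm]] <- list(dW = bk$dW, db = bk$db)
    dcat <- bk$dX
    dUp <- dcat[, , seq_len(enc_ch[i]), drop = FALSE]
    dEnc[[i]] <- dcat[, , enc_ch[i] + seq_len(enc_ch[i]), drop = FALSE]
    nm <- paste0("up", i)
    dUp <- dUp * cache[[paste0("R_", nm)]]
    bk <- convBackward(dUp, cache[[paste0("P_", nm)]], pr[[nm]]$W, h, w,
                       enc_ch[i + 1L])
    grads[[nm]] <- list(dW = bk$dW, db = bk$db)
    dA <- downsum2(bk$dX)
  }
  # dA now reaches the bottom encoder block
  for (i in rev(seq_len(D))) {
    if (i < D) {
      dPooled <- dA
      h <- dim(cache[[paste0("R_", paste0("enc", i, "b"))]])[1L]
      w <- dim(cache[[paste0("R_", paste0("enc", i, "b"))]])[2L]
      dA <- poolBackward(dPooled, cache[[paste0("arg", i)]], h, w)
      dA <- dA + dEnc[[i]]
    }
    for (s in c("b", "a")) {
      nm <- paste0("enc", i, s)
      dA <- dA * cache[[paste0("R_", nm)]]
      cin <- if (s == "b") enc_ch[i] else
        if (i == 1L) cfg@inSections else enc_ch[i - 1L]
      h <- dim(dA)[1L]; w <- dim(dA)[2L]
      bk <- convBackward(dA, cache[[paste0("P_", nm)]], pr[[nm]]$W, h, w, cin)
      grads[[nm]] <- list(dW = bk$dW, db = bk$db)
      dA <- bk$dX
    }
  }
  grads
}

bceLoss <- function(prob, target, weights, posWeight = 1) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  per <- -(posWeight * target * log(p) + (1 - target) * log(1 - p))
  sum(sweep(per, 3L, weights, "*")) / (dim(prob)[1L] * dim(prob)[2L])
}

adamStep <- function(model, grads, totalSteps = NULL) {
  cfg <- model$config
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (is.null(model$adam))
    model$adam <- lapply(model$params, function(p)
      list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
  model$step <- model$step + 1L
  base <- cfg@learningRate
  if (!is.null(totalSteps) && totalSteps > 0)   # cosine decay to 10%
    base <- base * (0.1 + 0.45 * (1 + cos(pi * min(model$step / totalSteps,
                                                   1))))
  lr <- base * sqrt(1 - b2^model$step) / (1 - b1^model$step)
  for (nm in names(grads)) {
    g <- grads[[nm]]; a <- model$adam[[nm]]
    a$mW <- b1 * a$mW + (1 - b1) * g$dW
    a$vW <- b2 * a$vW + (1 - b2) * g$dW^2
    a$mb <- b1 * a$mb + (1 - b1) * g$db
    a$vb <- b2 * a$vb + (1 - b2) * g$db^2
    model$params[[nm]]$W <- model$params[[nm]]$W - lr * a$mW / (sqrt(a$vW) + eps)
    model$params[[nm]]$b <- model$params[[nm]]$b - lr * a$mb / (sqrt(a$vb) + eps)
    model$adam[[nm]] <- a
  }
  model
}

asInputArray <- function(img, inSections) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] != inSections)
    stop("image has ", dim(img)[3L], " sections; model expects ", inSections)
  # centre and rescale: bright-field stacks live on [0,1] about a mid-grey
  # background, and a zero-mean input conditions the first layers far better
  (img - 0.5) * 2
}

targetArray <- function(tg) {
  if (is(tg, "SemanticTargets")) channels(tg) else tg
}

#' Train the U-net on paired images and semantic targets
#'
#' Adam on per-channel weighted binary cross-entropy, one image per step by
#' default (training is on single images). When `groups` (colony identities)
#' are supplied, validation images are held out by whole group so that no
#' colony contributes to both splits.
#'
#' @param model a model from [buildUnet()].
#' @param images list of H x W x nZ arrays (or matrices when `inSections`
#'   is 1).
#' @param targets list of binary [SemanticTargets-class] (or H x W x 8
#'   arrays) aligned with `images`.
#' @param groups optional group (colony) id per image for the held-out split.
#' @param valFraction fraction of groups (or images) held out.
#' @return list(model, history) where history is a data.frame with one row
#'   per epoch (epoch, train_loss, val_loss).
#' @export
trainUnet <- function(model, images, targets, groups = NULL,
                      valFraction = 0.2) {
  if (!length(images)) stop("empty training set")
  cfg <- model$config
  set.seed(cfg@seed + 1L)
  n <- length(images)
  if (is.null(groups)) groups <- seq_len(n)
  gs <- unique(groups)
  nVal <- max(0L, round(valFraction * length(gs)))
  valG <- if (nVal > 0L) sample(gs, nVal) else c()
  valIdx <- which(groups %in% valG)
  trIdx <- setdiff(seq_len(n), valIdx)
  if (!length(trIdx)) stop("no training images left after the split")
  xs <- lapply(images, asInputArray, inSections = cfg@inSections)
  ys <- lapply(targets, targetArray)
  mult <- 2L^cfg@depth
  evalLoss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    mean(vapply(idx, function(i) {
      px <- padToMultiple(xs[[i]], mult, value = 0)
      py <- padToMultiple(ys[[i]], mult, 0)
      fw <- unetForward(model, px$A)
      bceLoss(fw$prob, py$A, cfg@channelWeights, cfg@posWeight)
    }, numeric(1)))
  }
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  totalSteps <- cfg@epochs * ceiling(length(trIdx) / cfg@batchSize)
  val0 <- evalLoss(valIdx)
  for (ep in seq_len(cfg@epochs)) {
    ord <- sample(trIdx)
    losses <- numeric(0)
    bs <- cfg@batchSize
    for (bstart in seq(1L, length(ord), by = bs)) {
      batch <- ord[bstart:min(bstart + bs - 1L, length(ord))]
      agg <- NULL
      for (i in batch) {
        px <- padToMultiple(xs[[i]], mult, value = 0)
        py <- padToMultiple(ys[[i]], mult, 0)
        fw <- unetForward(model, px$A, keepCache = TRUE)
        losses <- c(losses, bceLoss(fw$prob, py$A, cfg@channelWeights, cfg@posWeight))
        g <- unetBackward(model, fw, py$A)
        if (is.null(agg)) agg <- g else
          for (nm in names(g)) {
            agg[[nm]]$dW <- agg[[nm]]$dW + g[[nm]]$dW
            agg[[nm]]$db <- agg[[nm]]$db + g[[nm]]$db
          }
      }
      if (length(batch) > 1L)
        for (nm in names(agg)) {
          agg[[nm]]$dW <- agg[[nm]]$dW / length(batch)
          agg[[nm]]$db <- agg[[nm]]$db / length(batch)
        }
      model <- adamStep(model, agg, totalSteps = totalSteps)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = evalLoss(valIdx)))
  }
  list(model = model, history = hist, initialValLoss = val0)
}

#' Predict the eight-channel semantic maps for one Z-stack
#'
#' @param model a (typically trained) model from [buildUnet()].
#' @param zstack H x W x nZ array (or H x W matrix for single-section
#'   models); padded internally when H or W is not divisible by
#'   2^depth and cropped back.
#' @return A probability [SemanticTargets-class].
#' @export
predictSemantic <- function(model, zstack) {
  cfg <- model$config
  x <- asInputArray(zstack, cfg@inSections)
  pd <- padToMultiple(x, 2L^cfg@depth, value = 0)
  fw <- unetForward(model, pd$A)
  SemanticTargets(fw$prob[seq_len(pd$H), seq_len(pd$W), , drop = FALSE],
                  binary = FALSE)
}

#' Ideal-CNN bypass: semantic maps straight from ground truth
#'
#' Returns the binary target stack of an annotated frame cast to
#' probabilities, optionally blurred with a Gaussian of sd `sigma` to mimic
#' the softness of CNN output. With `sigma = 0` this is exactly
#' [buildTargetStack()].
#'
#' @param frame an [AnnotatedFrame-class] (ground truth).
#' @param spec a [SizeCategorySpec-class].
#' @param sigma blur sd in px (0 = none).
#' @return A probability [SemanticTargets-class].
#' @export
oraclePredict <- function(frame, spec, sigma = 0) {
  ch <- channels(buildTargetStack(frame, spec))
  if (sigma > 0)
    for (i in seq_len(dim(ch)[3L]))
      ch[, , i] <- pmin(pmax(
        asMaskMatrix(EBImage::gblur(ch[, , i], sigma = sigma)), 0), 1)
  SemanticTargets(ch, binary = FALSE)
}

#' Pixel F1 of thresholded predictions against binary targets
#'
#' @param pred a probability [SemanticTargets-class] (or array).
#' @param truth a binary [SemanticTargets-class] (or array).
#' @param channelIdx channels to pool (default the three interiors).
#' @param threshold probability threshold.
#' @return F1 in [0,1] (1 when both are empty).
#' @export
pixelF1 <- function(pred, truth, channelIdx = 1:3, threshold = 0.5) {
  p <- targetArray(pred)[, , channelIdx, drop = FALSE] >= threshold
  y <- targetArray(truth)[, , channelIdx, drop = FALSE] >= 0.5
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Build a paired U-net training set from simulated colonies
#'
#' Simulates one single-mother colony per seed, derives a shared
#' size-category specification from all frames unless one is given, and
#' returns aligned Z-stacks, binary target stacks and colony identifiers
#' for a grouped train/validation split. Five Z sections are rendered by
#' default: small buds sit away from the central focal plane, and the
#' off-focus sections are what make them detectable.
#'
#' @param seeds one colony per seed.
#' @param nFrames frames per colony.
#' @param imageShape image size in px (divisible by 2^depth avoids padding).
#' @param nZ Z sections per stack (1 or 5).
#' @param spec optional [SizeCategorySpec-class] to reuse (e.g. for a test
#'   set scored against a training spec).
#' @return list(images, targets, groups, spec).
#' @export
simulateTrainingSet <- function(seeds, nFrames = 10L,
                                imageShape = c(64L, 64L), nZ = 5L,
                                spec = NULL) {
  mvs <- lapply(seeds, function(s) simulateColony(
    SimParams(imageShape = imageShape, nZ = nZ, nTimepoints = nFrames,
              nMothers = 1L, motherRadiusRange = c(8, 11), seed = s)))
  if (is.null(spec))
    spec <- optimizeSizeBoundaries(unlist(lapply(mvs, frames)))
  imgs <- list(); tgts <- list(); groups <- integer()
  for (i in seq_along(mvs)) for (t in seq_len(nFrames)) {
    imgs[[length(imgs) + 1L]] <- images(mvs[[i]])[[t]]
    tgts[[length(tgts) + 1L]] <- buildTargetStack(frames(mvs[[i]])[[t]],
                                                  spec)
    groups <- c(groups, seeds[i])
  }
  list(images = imgs, targets = tgts, groups = groups, spec = spec)
}
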