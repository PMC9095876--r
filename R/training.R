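#' @include networks.R
NULL

#' Construct a training configuration
#'
#' Defaults follow the training recipe: Adam with learning rate 2e-4 and
#' betas (0.5, 0.999), L2 regularization 1e-5, 200 epochs, x/y flip
#' probability 0.5, and MS-SSIM validation checkpointing.  Pass small
#' \code{epochs} and batch sizes for desk-scale runs.
#'
#' @param mode "orpam3d", "pretrain2d" or "pact2d" (selects the loss).
#' @param epochs training epochs (>= 0; 0 skips training and returns the
#'   initial weights).
#' @param learningRate,beta1,beta2 Adam hyperparameters.
#' @param l2 L2 regularization coefficient.
#' @param maxGradNorm global gradient-norm clip applied before each Adam
#'   update (default 1; Inf disables).  Guards the early epochs against
#'   saturating the output nonlinearity.
#' @param batchSize gradient-accumulation batch size.
#' @param cropSize integer vector random-crop size (e.g. \code{c(64,64,64)}
#'   for 3D, \code{c(512,768)} for 2D), or NULL for no cropping.
#' @param flipProb x/y flip probability in augmentation.
#' @param seed master seed.
#' @param metricConfig \linkS4class{MetricConfig} for the MS-SSIM loss term
#'   and validation metric.
#' @return a \linkS4class{TrainConfig}.
#' @export
TrainConfig <- function(mode = c("orpam3d", "pretrain2d", "pact2d"),
                        epochs = 200L, learningRate = 2e-4, beta1 = 0.5,
                        beta2 = 0.999, l2 = 1e-5, maxGradNorm = 1,
                        batchSize = 2L,
                        cropSize = NULL, flipProb = 0.5, seed = 1L,
                        metricConfig = MetricConfig()) {
  new("TrainConfig", mode = match.arg(mode), epochs = as.integer(epochs),
      learningRate = learningRate, beta1 = beta1, beta2 = beta2, l2 = l2,
      maxGradNorm = maxGradNorm, batchSize = as.integer(batchSize),
      cropSize = if (is.null(cropSize)) NULL else as.numeric(cropSize),
      flipProb = flipProb, seed = as.integer(seed),
      metricConfig = metricConfig)
}

checkProb <- function(p, what = "d_prob") {
  if (any(p <= 0) || any(p >= 1))
    stop(sprintf("invalid argument: %s must be in (0, 1)", what))
  invisible(p)
}

#' Generator losses and the discriminator loss
#'
#' Closed-form training objectives.  The volumetric (3D) generator loss is
#' \deqn{0.01 \cdot \frac{1}{N}\sum |y - G(x)| - \log D(G(x)),}
#' the 2D pre-training loss (transfer-learning stage, no adversary)
#' \deqn{0.3 \cdot \mathrm{MAE} + 0.7 \cdot (1 - \mathrm{MSSSIM}(y, G(x))),}
#' and the full 2D loss
#' \deqn{0.03 \cdot \mathrm{MAE} + 0.07 \cdot (1 - \mathrm{MSSSIM}) - \log D(G(x)),}
#' with N the pixel count.  The discriminator minimizes
#' \deqn{-[\log D(y) + \log(1 - D(G(x)))],} the negated adversarial min-max
#' objective.  \code{dProb} may be a scalar or a patch-probability array, in
#' which case the adversarial term is averaged over patches.
#'
#' @param y dense target array.
#' @param gOut generator output array, same shape.
#' @param dProb discriminator probability (scalar or array) in (0, 1).
#' @param pixelCount N, defaults to \code{length(y)}.
#' @param config \linkS4class{MetricConfig} for the MS-SSIM term.
#' @return numeric scalar loss.
#' @examples
#' y <- matrix(runif(16 * 16), 16)
#' lossGenerator3d(y, y, 0.5) # -log(0.5)
#' lossPretrain2d(y, y)       # 0
#' @name losses
#' @rdname losses
#' @export
lossGenerator3d <- function(y, gOut, dProb, pixelCount = length(y)) {
  stopifnot(identical(dim(y), dim(gOut)))
  checkProb(dProb)
  0.01 * sum(abs(y - gOut)) / pixelCount + mean(-log(dProb))
}

#' @rdname losses
#' @export
lossPretrain2d <- function(y, gOut, pixelCount = length(y),
                           config = MetricConfig()) {
  stopifnot(identical(dim(y), dim(gOut)))
  0.3 * sum(abs(y - gOut)) / pixelCount + 0.7 * (1 - msSSIM(y, gOut, config))
}

#' @rdname losses
#' @export
lossGenerator2d <- function(y, gOut, dProb, pixelCount = length(y),
                            config = MetricConfig()) {
  stopifnot(identical(dim(y), dim(gOut)))
  checkProb(dProb)
  0.03 * sum(abs(y - gOut)) / pixelCount +
    0.07 * (1 - msSSIM(y, gOut, config)) + mean(-log(dProb))
}

#' @rdname losses
#' @param dRealProb,dFakeProb discriminator probabilities on the dense image
#'   and on the generator output.
#' @export
lossDiscriminator <- function(dRealProb, dFakeProb) {
  checkProb(dRealProb, "dRealProb")
  checkProb(dFakeProb, "dFakeProb")
  -(mean(log(dRealProb)) + mean(log(1 - dFakeProb)))
}

# node-space generator loss matching the closed forms above
lossNode <- function(tape, mode, yc, gOut, dProb, config) {
  mae <- adMean(adAbs(adSub(gOut, yc, tape), tape), tape)
  advTerm <- function() {
    p <- adClamp01(dProb, 1e-7, tape)
    adScale(adMean(adLog(p, tape), tape), -1, tape)
  }
  oneMinusMs <- function() {
    ms <- adMsSSIM(gOut, yc, config, tape)
    adShift(adScale(ms, -1, tape), 1, tape)
  }
  switch(mode,
    orpam3d = adAdd(adScale(mae, 0.01, tape), advTerm(), tape),
    pretrain2d = adAdd(adScale(mae, 0.3, tape),
                       adScale(oneMinusMs(), 0.7, tape), tape),
    pact2d = adAdd(adAdd(adScale(mae, 0.03, tape),
                         adScale(oneMinusMs(), 0.07, tape), tape),
                   advTerm(), tape))
}

newAdamState <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(params, grads, state, lr, b1, b2, l2, clip = Inf,
                     eps = 1e-8) {
  if (is.finite(clip)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm > clip) grads <- lapply(grads, function(g) g * clip / gnorm)
  }
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] %||% 0
    g <- g + l2 * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Augment a paired sample
#'
#' Applies the identical random crop and x/y flips to input and target,
#' preserving their spatial registration.
#'
#' @param sample a \linkS4class{PairedSample}.
#' @param cropSize integer spatial crop size per axis, or NULL for no crop.
#' @param flipProb per-axis flip probability for the x and y axes.
#' @param seed optional seed; NULL uses the current RNG stream.
#' @return an augmented \linkS4class{PairedSample}.
#' @export
augmentPair <- function(sample, cropSize = NULL, flipProb = 0.5, seed = NULL) {
  doAug <- function() {
    x <- sample@x; y <- sample@y
    dy <- dim(y)
    nd <- length(dy)
    if (!is.null(cropSize)) {
      cs <- as.integer(cropSize)
      if (length(cs) != nd || any(cs > dy))
        stop("invalid argument: crop larger than sample")
      orig <- vapply(seq_len(nd), function(d)
        if (dy[d] == cs[d]) 1L else sample.int(dy[d] - cs[d] + 1L, 1L),
        integer(1))
      idx <- lapply(seq_len(nd), function(d) orig[d]:(orig[d] + cs[d] - 1L))
      y <- do.call(`[`, c(list(y), idx, list(drop = FALSE)))
      x <- do.call(`[`, c(list(x), idx, list(TRUE), list(drop = FALSE)))
    }
    for (d in 1:2) { # flips in x and y only
      if (stats::runif(1) < flipProb) {
        ridx <- lapply(seq_len(nd), function(dd)
          if (dd == d) rev(seq_len(dim(y)[dd])) else seq_len(dim(y)[dd]))
        y <- do.call(`[`, c(list(y), ridx, list(drop = FALSE)))
        x <- do.call(`[`, c(list(x), ridx, list(TRUE), list(drop = FALSE)))
      }
    }
    new("PairedSample", x = x, y = y)
  }
  if (is.null(seed)) doAug() else withSeed(seed, doAug())
}

samplesOf <- function(set) {
  if (is(set, "DatasetBundle")) set@samples else set
}

#' Train a generator (optionally adversarially) on paired samples
#'
#' Alternates one discriminator and one generator update per batch (gradient
#' accumulation within the batch), evaluates validation MS-SSIM after every
#' epoch, and keeps the parameters of the epoch with the highest validation
#' MS-SSIM as the checkpoint.  Fully seeded: identical configurations
#' reproduce identical loss trajectories.  A non-finite loss aborts with a
#' condition of class \code{palocalDivergence} carrying the partial record.
#'
#' @param generator a generator \linkS4class{PANetwork}.
#' @param discriminator a discriminator \linkS4class{PANetwork}, or NULL for
#'   the adversary-free pre-training mode.
#' @param trainSet,valSet lists of \linkS4class{PairedSample} (or
#'   \linkS4class{DatasetBundle}s); both non-empty.
#' @param config a \linkS4class{TrainConfig}.
#' @return list with elements \code{generator} (checkpointed network),
#'   \code{lastGenerator}, \code{discriminator}, \code{record} (per-epoch
#'   data.frame with gLoss, dLoss, valMSSSIM), \code{bestEpoch} and
#'   \code{lossFunction}.
#' @export
fitGAN <- function(generator, discriminator, trainSet, valSet, config) {
  validObject(config)
  trainSet <- samplesOf(trainSet)
  valSet <- samplesOf(valSet)
  if (!length(trainSet) || !length(valSet))
    stop("invalid argument: train and validation sets must be non-empty")
  mode <- config@mode
  adversarial <- mode %in% c("orpam3d", "pact2d")
  if (adversarial && is.null(discriminator))
    stop("invalid argument: adversarial modes need a discriminator")

  # pin the MS-SSIM scale count once so every evaluation uses the same scales
  mcfg <- config@metricConfig
  if (is.null(mcfg@scales)) {
    dmProbe <- dim(valSet[[1]]@y)
    if (!is.null(config@cropSize)) dmProbe <- pmin(dmProbe, config@cropSize)
    feas <- maxFeasibleScales(dmProbe, mcfg@windowSize)
    mcfg@scales <- as.numeric(min(length(mcfg@weights), feas))
  }

  gp <- generator@params
  dp <- if (adversarial) discriminator@params else NULL
  gState <- newAdamState(gp)
  dState <- if (adversarial) newAdamState(dp) else NULL

  valScore <- function(params) {
    g2 <- initialize(generator, params = params)
    mean(vapply(valSet, function(s)
      msSSIM(networkForward(g2, s@x), s@y, mcfg), numeric(1)))
  }

  rec <- data.frame(epoch = integer(0), gLoss = numeric(0),
                    dLoss = numeric(0), valMSSSIM = numeric(0))
  if (config@epochs == 0L) {
    return(list(generator = generator, lastGenerator = generator,
                discriminator = discriminator, record = rec,
                bestEpoch = 0L, lossFunction = mode))
  }
  # the starting weights are an epoch-0 checkpoint candidate: if no epoch
  # improves on them, training returns them (early stopping at 0 updates)
  best <- list(score = valScore(gp), params = gp, epoch = 0L)

  withSeed(config@seed, {
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(length(trainSet))
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      gLossSum <- 0; dLossSum <- 0; nB <- 0L
      for (bi in batches) {
        samples <- lapply(trainSet[bi], function(s)
          if (is.null(config@cropSize) && config@flipProb == 0) s
          else augmentPair(s, config@cropSize, config@flipProb))
        nb <- length(samples)

        if (adversarial) {
          # discriminator step on detached generator outputs
          dGrads <- NULL; dLoss <- 0
          genNow <- initialize(generator, params = gp)
          for (s in samples) {
            gv <- networkForward(genNow, s@x)
            tape <- newTape()
            pnD <- paramNodes(tape, dp)
            dReal <- discForward(tape, discriminator,
                                 adLeaf(tape, addChannelDim(s@y)), pnD)
            dFake <- discForward(tape, discriminator,
                                 adLeaf(tape, addChannelDim(gv)), pnD)
            lossD <- adAdd(
              adScale(adMean(adLog(adClamp01(dReal, 1e-7, tape), tape), tape),
                      -1, tape),
              adScale(adMean(adLog(adShift(adScale(
                adClamp01(dFake, 1e-7, tape), -1, tape), 1, tape), tape), tape),
                -1, tape), tape)
            adBackward(tape, lossD)
            dLoss <- dLoss + lossD$value
            dGrads <- accumGrads(dGrads, pnD, 1 / nb)
          }
          upd <- adamStep(dp, dGrads, dState, config@learningRate,
                          config@beta1, config@beta2, config@l2,
                          config@maxGradNorm)
          dp <- upd$params; dState <- upd$state
          discriminator@params <- dp
          dLossSum <- dLossSum + dLoss / nb
        }

        # generator step
        gGrads <- NULL; gLoss <- 0
        for (s in samples) {
          tape <- newTape()
          pnG <- paramNodes(tape, gp)
          xn <- adLeaf(tape, s@x)
          yc <- adLeaf(tape, s@y)
          gOutC <- genForward(tape, generator, xn, pnG, train = TRUE)
          gOut <- dropChannelNode(gOutC, tape)
          dProb <- NULL
          if (adversarial) {
            pnD <- paramNodes(tape, dp)
            dProb <- discForward(tape, discriminator, gOutC, pnD)
          }
          loss <- lossNode(tape, mode, yc, gOut, dProb, mcfg)
          if (!is.finite(loss$value))
            divergenceAbort(rec, ep, loss$value)
          adBackward(tape, loss)
          gLoss <- gLoss + loss$value
          gGrads <- accumGrads(gGrads, pnG, 1 / nb)
        }
        upd <- adamStep(gp, gGrads, gState, config@learningRate,
                        config@beta1, config@beta2, config@l2,
                        config@maxGradNorm)
        gp <- upd$params; gState <- upd$state
        gLossSum <- gLossSum + gLoss / nb
        nB <- nB + 1L
      }
      vs <- valScore(gp)
      rec <- rbind(rec, data.frame(epoch = ep, gLoss = gLossSum / nB,
                                   dLoss = if (adversarial) dLossSum / nB else NA_real_,
                                   valMSSSIM = vs))
      if (vs > best$score) best <- list(score = vs, params = gp, epoch = ep)
    }
  })

  list(generator = initialize(generator, params = best$params),
       lastGenerator = initialize(generator, params = gp),
       discriminator = if (adversarial) discriminator else NULL,
       record = rec, bestEpoch = best$epoch, lossFunction = mode)
}

addChannelDim <- function(a) {
  if (is.null(dim(a))) dim(a) <- length(a)
  array(a, dim = c(dim(a), 1L))
}

# drop the generator's singleton channel axis (value and gradient reshaped)
dropChannelNode <- function(x, tape) {
  dm <- dim(x$value)
  v <- array(x$value, dim = dm[-length(dm)])
  adNode(tape, v, list(x), function(g) list(array(g, dim = dm)))
}

accumGrads <- function(acc, pn, scale) {
  if (is.null(acc)) acc <- list()
  for (nm in names(pn)) {
    g <- pn[[nm]]$grad
    if (is.null(g)) next
    acc[[nm]] <- (acc[[nm]] %||% 0) + scale * g
  }
  acc
}

divergenceAbort <- function(record, epoch, value) {
  cond <- structure(
    class = c("palocalDivergence", "error", "condition"),
    list(message = sprintf(
      "training diverged at epoch %d (non-finite loss %s)", epoch, value),
      call = NULL, record = record))
  stop(cond)
}

#' Fine-tune a pre-trained 2D generator on PACT-style pairs
#'
#' The transfer-learning handoff: a generator pre-trained on OR-PAM
#' maximum-amplitude-projection pairs with the MAE + MS-SSIM loss is further
#' trained on the (smaller) PACT dataset with the full adversarial loss and a
#' freshly initialized discriminator.  The returned record documents the loss
#' switch.
#'
#' @param pretrained the pre-trained generator (a 2D \linkS4class{PANetwork},
#'   typically \code{fitGAN(..., mode = "pretrain2d")$generator}).
#' @param pactTrain,pactVal PACT-style paired samples.
#' @param config a \linkS4class{TrainConfig} with \code{mode = "pact2d"}.
#' @param discSpec \linkS4class{DiscriminatorSpec} for the fresh adversary.
#' @return as \code{\link{fitGAN}}, with \code{lossFunction =
#'   c(pretrain = "pretrain2d", finetune = "pact2d")}.
#' @export
transferFinetune <- function(pretrained, pactTrain, pactVal, config,
                             discSpec = DiscriminatorSpec(dim = 2L,
                                                          baseWidth = 8L)) {
  if (!is(pretrained, "PANetwork") || pretrained@role != "generator")
    stop("invalid argument: pretrained must be a generator network")
  if (pretrained@spec@dim != 2L)
    stop("invalid argument: transfer learning applies to the 2D generator (dim mismatch)")
  if (config@mode != "pact2d")
    stop("invalid argument: fine-tuning uses mode 'pact2d'")
  disc <- buildDiscriminator(discSpec, seed = config@seed + 1L)
  fit <- fitGAN(pretrained, disc, pactTrain, pactVal, config)
  fit$lossFunction <- c(pretrain = "pretrain2d", finetune = "pact2d")
  fit
}
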