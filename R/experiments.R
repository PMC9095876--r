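#' @include training.R pairs.R
NULL

#' Desk-scale sparse-to-dense learning experiment
#'
#' The scaled-down analogue of the frame-count studies: synthesize paired
#' sparse/dense localization images from independent vascular phantoms and
#' train the 2D generator with the full transfer-learning schedule --
#' MAE + MS-SSIM pre-training on an OR-PAM maximum-amplitude-projection-style
#' corpus (frame-wise, max-accumulated, hence bright), then adversarial
#' fine-tuning with a fresh discriminator on the PACT-style corpus
#' (droplet-wise, sum-accumulated) -- and compare held-out MS-SSIM of the
#' generator output against the sparse input itself, over several training
#' seeds.  Pre-training on the brighter MAP-style domain also stabilizes
#' optimization: trained cold on the sparse dark PACT images, some seeds
#' collapse to a constant dark output.  Default sizes (64 training pairs of
#' 64 x 64 pixels, 35 + 15 epochs, an 8-channel two-level generator, random
#' 32 x 32 crops) are the package's desk-scale study conditions.
#'
#' @param seeds integer vector of training seeds (one run per seed).
#' @param nTrain,nVal training and held-out pair counts.
#' @param gridShape pair image shape.
#' @param nFrames dense frame count N.
#' @param k sparse frame count (the 60 to 5 operating point reduces
#'   acquisition 12-fold).
#' @param absorbersPerFrame flowing absorbers per frame.
#' @param epochsPretrain,epochsFinetune epochs of the two stages.
#' @param baseWidth,levels desk-scale generator size.
#' @param learningRate,batchSize optimizer settings for the desk scale.
#' @param cropSize random-crop augmentation size.
#' @param dataSeed seed of the synthetic dataset.
#' @return data.frame with one row per seed: baseline (sparse-vs-dense
#'   MS-SSIM), dnn (generator-vs-dense MS-SSIM) and improved (dnn > baseline),
#'   with the per-seed training records in attribute \code{records}.
#' @export
sparseToDenseExperiment <- function(seeds = c(1L, 2L, 3L), nTrain = 64L,
                                    nVal = 16L, gridShape = c(64L, 64L),
                                    nFrames = 60L, k = 5L,
                                    absorbersPerFrame = 25L,
                                    epochsPretrain = 35L, epochsFinetune = 15L,
                                    baseWidth = 8L, levels = 2L,
                                    learningRate = 1e-3, batchSize = 4L,
                                    cropSize = c(32L, 32L), dataSeed = 101L) {
  mapPairs <- makeLocalizationPairs(nTrain + nVal, dim = 2L,
                                    gridShape = gridShape, nFrames = nFrames,
                                    k = k,
                                    absorbersPerFrame = absorbersPerFrame,
                                    seed = dataSeed + 1L, style = "orpam_map")
  pairs <- makeLocalizationPairs(nTrain + nVal, dim = 2L,
                                 gridShape = gridShape, nFrames = nFrames,
                                 k = k, absorbersPerFrame = absorbersPerFrame,
                                 seed = dataSeed, style = "pact")
  mapTrain <- mapPairs[seq_len(nTrain)]
  mapVal <- mapPairs[nTrain + seq_len(nVal)]
  train <- pairs[seq_len(nTrain)]
  val <- pairs[nTrain + seq_len(nVal)]
  mcfg <- MetricConfig(scales = min(5, maxFeasibleScales(gridShape, 11L)))
  baseline <- mean(vapply(val, function(s)
    msSSIM(s@x[, , 1], s@y, mcfg), numeric(1)))

  records <- list()
  rows <- lapply(seeds, function(sd) {
    g <- buildGenerator(GeneratorSpec(dim = 2L, baseWidth = baseWidth,
                                      levels = levels), seed = sd)
    pre <- TrainConfig(mode = "pretrain2d", epochs = epochsPretrain,
                       learningRate = learningRate, batchSize = batchSize,
                       cropSize = cropSize, flipProb = 0.5, seed = sd)
    fit1 <- fitGAN(g, NULL, mapTrain, mapVal, pre)
    ft <- TrainConfig(mode = "pact2d", epochs = epochsFinetune,
                      learningRate = learningRate, batchSize = batchSize,
                      cropSize = cropSize, flipProb = 0.5, seed = sd + 100L)
    fit2 <- transferFinetune(fit1$generator, train, val, ft)
    dnn <- mean(vapply(val, function(s)
      msSSIM(networkForward(fit2$generator, s@x), s@y, mcfg), numeric(1)))
    records[[as.character(sd)]] <<- list(pretrain = fit1$record,
                                         finetune = fit2$record)
    data.frame(seed = sd, baseline = baseline, dnn = dnn,
               improved = dnn > baseline)
  })
  out <- do.call(rbind, rows)
  attr(out, "records") <- records
  out
}

#' Sparsity sweep: reconstruction quality versus frame count
#'
#' On a fixed synthetic series, reconstructs sparse localization images from
#' k randomly selected frames and scores them against the dense (all-N)
#' reconstruction with MS-SSIM, across selection seeds -- the mechanism
#' behind the frame-count quality curves: more frames give a denser, more
#' faithful superresolution image.
#'
#' @param ks frame counts to sweep.
#' @param nFrames dense frame count N.
#' @param seeds frame-selection seeds.
#' @param gridShape image shape.
#' @param absorbersPerFrame flowing absorbers per frame.
#' @param renderSigma localization-precision rendering sigma (pixels).
#' @param phantomSeed seed of the phantom and absorber trajectories.
#' @return data.frame with columns seed, k, msssim; Spearman rank
#'   correlations of msssim with k per seed in attribute \code{rho}.
#' @export
sparsitySweep <- function(ks = c(2L, 5L, 10L, 30L, 60L), nFrames = 60L,
                          seeds = 1:5, gridShape = c(64L, 64L),
                          absorbersPerFrame = 25L, renderSigma = 1,
                          phantomSeed = 7L) {
  stopifnot(max(ks) <= nFrames)
  cfg <- ImagingConfig(gridShape)
  region <- gridShape * cfg@pixelSize
  tree <- generateVesselTree(region, dim = 2L, depth = 3L,
                             seed = phantomSeed, nRoots = 2L)
  ev <- sampleAbsorbers(tree, absorbersPerFrame, nFrames,
                        seed = phantomSeed + 1L)
  eventSets <- lapply(seq_len(nFrames) - 1L, function(f) {
    e <- ev[ev$frame_index == f, , drop = FALSE]
    df <- data.frame(x = pmin(pmax(e$x / cfg@pixelSize[1] - 0.5, -0.5),
                              gridShape[1] - 0.5),
                     y = pmin(pmax(e$y / cfg@pixelSize[2] - 0.5, -0.5),
                              gridShape[2] - 0.5),
                     amplitude = e$amplitude, frame_index = f)
    new("LocalizationEvents", events = df, gridShape = as.integer(gridShape),
        superresFactor = 1L)
  })
  dense <- renderForTraining(makeDense(eventSets, mode = "max",
                                       unit = "frame"), renderSigma)
  mcfg <- MetricConfig(scales = min(5, maxFeasibleScales(gridShape, 11L)))
  out <- do.call(rbind, lapply(seeds, function(sd)
    do.call(rbind, lapply(ks, function(k) {
      sp <- renderForTraining(makeSparse(eventSets, k = k, seed = sd,
                                         mode = "max", unit = "frame"),
                              renderSigma)
      data.frame(seed = sd, k = k, msssim = msSSIM(sp, dense, mcfg))
    }))))
  rho <- vapply(split(out, out$seed), function(d)
    stats::cor(d$k, d$msssim, method = "spearman"), numeric(1))
  attr(out, "rho") <- rho
  out
}
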