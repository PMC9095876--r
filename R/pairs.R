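#' @include localization.R phantom.R
NULL

# normalize a non-negative array to [0, 1]
norm01 <- function(a) if (max(a) > 0) a / max(a) else a

# render a localization image for training: optional Gaussian smoothing with
# the localization-precision sigma, then renormalization
renderForTraining <- function(img, sigma) {
  a <- asArray(img)
  if (sigma > 0) a <- norm01(gaussSmooth(a, sigma))
  a
}

#' Synthesize sparse/dense localization training pairs
#'
#' Builds paired samples from independent synthetic vascular phantoms: for
#' each sample a vessel tree is grown, flowing absorbers are sampled over
#' \code{nFrames} frames, and sparse (k of N) and dense (all N) localization
#' images are reconstructed.  In 2D (PACT-style) selection is droplet-wise
#' with sum accumulation and the generator input is the sparse image alone;
#' in 3D (OR-PAM-style) selection is frame-wise with max accumulation and
#' the input gains a second channel holding one regular (diffraction-limited)
#' frame.  With \code{events = "truth"} the simulator's absorber positions
#' are used directly (ground-truth localization); \code{"detected"} runs the
#' full render-and-localize pipeline.  Both localization images are rendered
#' with a Gaussian of \code{renderSigma} pixels, emulating the finite
#' localization precision of superresolution reconstructions.
#'
#' @param nSamples number of pairs.
#' @param dim 2 or 3.
#' @param gridShape source grid shape.
#' @param nFrames total frames N.
#' @param k frames (3D) or droplets (2D) in the sparse image; droplet counts
#'   are \code{k} times the per-frame absorber count in 2D.
#' @param absorbersPerFrame flowing absorbers per frame.
#' @param seed master seed; per-sample seeds derive from it.
#' @param factor superresolution factor of the localization grid.
#' @param events "truth" or "detected".
#' @param renderSigma rendering sigma in pixels (0 disables smoothing).
#' @param treeDepth phantom branching depth.
#' @param config optional \linkS4class{ImagingConfig}; defaults to the
#'   modality defaults for \code{gridShape}.
#' @param threshold detection threshold for \code{events = "detected"}.
#' @param style 2D corpus style: "pact" (droplet-wise selection, sum
#'   accumulation -- the fine-tuning target domain) or "orpam_map"
#'   (frame-wise selection, max accumulation, emulating OR-PAM
#'   maximum-amplitude-projection images -- the pre-training corpus of the
#'   transfer-learning schedule).  Ignored in 3D.
#' @return list of \linkS4class{PairedSample}.
#' @export
makeLocalizationPairs <- function(nSamples, dim = 2L, gridShape = c(64, 64),
                                  nFrames = 60L, k = 5L,
                                  absorbersPerFrame = 25L, seed = 1L,
                                  factor = 1L, events = c("truth", "detected"),
                                  renderSigma = 1, treeDepth = 3L,
                                  config = NULL, threshold = 0.2,
                                  style = c("pact", "orpam_map")) {
  events <- match.arg(events)
  style <- match.arg(style)
  dim <- as.integer(dim)
  stopifnot(length(gridShape) == dim)
  if (is.null(config)) config <- ImagingConfig(gridShape)
  mapStyle <- dim == 3L || style == "orpam_map"
  mode <- if (mapStyle) "max" else "sum"
  unit <- if (mapStyle) "frame" else "droplet"
  region <- gridShape * config@pixelSize

  lapply(seq_len(nSamples), function(i) {
    si <- as.integer((as.numeric(seed) + i * 7919) %% 2147483647)
    tree <- generateVesselTree(region, dim = dim, depth = treeDepth, seed = si,
                               nRoots = 2L)
    if (events == "truth") {
      ev <- sampleAbsorbers(tree, absorbersPerFrame, nFrames, seed = si + 1L)
      eventSets <- lapply(seq_len(nFrames) - 1L, function(f) {
        e <- ev[ev$frame_index == f, , drop = FALSE]
        pos <- sweep(as.matrix(e[, c("x", "y", "z")[seq_len(dim)], drop = FALSE]),
                     2, config@pixelSize, `/`) - 0.5
        df <- as.data.frame(pos)
        names(df) <- c("x", "y", "z")[seq_len(dim)]
        df$amplitude <- e$amplitude
        df$frame_index <- f
        for (d in seq_len(dim)) {
          nm <- c("x", "y", "z")[d]
          df[[nm]] <- pmin(pmax(df[[nm]], -0.5), gridShape[d] - 0.5)
        }
        new("LocalizationEvents", events = df,
            gridShape = as.integer(gridShape), superresFactor = 1L)
      })
    } else {
      series <- renderSeries(tree, nFrames, absorbersPerFrame, config,
                             seed = si + 1L)
      eventSets <- localizeSeries(series, threshold = threshold)
    }
    kUse <- if (unit == "droplet")
      min(k * absorbersPerFrame,
          sum(vapply(eventSets, function(s) nrow(localEvents(s)), numeric(1))))
    else k
    dense <- makeDense(eventSets, factor = factor, mode = mode, unit = unit)
    sparse <- makeSparse(eventSets, k = kUse, seed = si + 2L, factor = factor,
                         mode = mode, unit = unit)
    yD <- renderForTraining(dense, renderSigma)
    xS <- renderForTraining(sparse, renderSigma)
    if (dim == 3L) {
      ev0 <- if (events == "truth") ev[ev$frame_index == 0, , drop = FALSE]
             else series@events[series@events$frame_index == 0, , drop = FALSE]
      reg <- withSeed(si + 3L, suppressWarnings(renderFrame(ev0, config)))
      x <- array(c(xS, reg), dim = c(dim(yD), 2L))
    } else {
      x <- array(xS, dim = c(dim(yD), 1L))
    }
    new("PairedSample", x = x, y = yD)
  })
}
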