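#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Imaging configuration for the simulated photoacoustic forward model
#'
#' Describes the sampling grid and point-spread function (PSF) of a regular
#' photoacoustic acquisition.  Defaults emulate an optical-resolution
#' photoacoustic microscopy (OR-PAM) scanner with lateral pixel sizes of
#' 3.75 and 5 micrometers, a 3 micrometer axial pixel, an optical-diffraction
#' scale lateral PSF and an acoustically limited axial PSF; a 2D configuration
#' with a 25 micrometer pixel emulates planar photoacoustic computed
#' tomography (PACT).
#'
#' @slot gridShape integer vector, number of pixels per axis (length 2 or 3).
#' @slot pixelSize numeric vector, physical pixel size per axis in micrometers.
#' @slot psfFWHM numeric vector, PSF full width at half maximum per axis in
#'   micrometers; must be at least one pixel on each axis.
#' @slot noiseSD numeric, standard deviation of additive Gaussian noise on the
#'   normalized amplitude scale.
#' @slot background numeric, constant background level in [0, 1).
#' @export
setClass("ImagingConfig",
  representation(gridShape = "integer", pixelSize = "numeric",
                 psfFWHM = "numeric", noiseSD = "numeric",
                 background = "numeric"))

setValidity("ImagingConfig", function(object) {
  n <- length(object@gridShape)
  if (!n %in% c(2L, 3L)) return("gridShape must have length 2 or 3")
  if (length(object@pixelSize) != n || length(object@psfFWHM) != n)
    return("pixelSize and psfFWHM must match gridShape length")
  if (any(object@gridShape < 1L)) return("gridShape entries must be >= 1")
  if (any(object@pixelSize <= 0)) return("pixel sizes must be positive")
  if (any(object@psfFWHM < object@pixelSize))
    return("PSF FWHM must be >= pixel size on each axis")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@background < 0 || object@background >= 1)
    return("background must be in [0, 1)")
  TRUE
})

#' Synthetic vessel tree phantom
#'
#' A branching set of cylindrical (3D) or ribbon-like (2D) vessel segments
#' standing in for imaged microvasculature.  Segment endpoints are physical
#' coordinates in micrometers with the origin at the grid corner.
#'
#' @slot segments data.frame with columns \code{x0,y0,z0,x1,y1,z1,radius,depth,
#'   parent}; in 2D the z columns are zero.
#' @slot region numeric vector, physical extent per axis in micrometers.
#' @slot dim integer, 2 or 3.
#' @export
setClass("VesselTree",
  representation(segments = "data.frame", region = "numeric", dim = "integer"))

setValidity("VesselTree", function(object) {
  if (!object@dim %in% c(2L, 3L)) return("dim must be 2 or 3")
  if (length(object@region) != object@dim || any(object@region <= 0))
    return("region must be positive on each of dim axes")
  s <- object@segments
  need <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "depth", "parent")
  if (!all(need %in% names(s))) return("segments missing required columns")
  if (nrow(s) > 0) {
    if (any(s$radius <= 0)) return("segment radii must be > 0")
    ext <- c(object@region, Inf, Inf)[seq_len(3)]
    pts <- rbind(as.matrix(s[, c("x0", "y0", "z0")]),
                 as.matrix(s[, c("x1", "y1", "z1")]))
    if (any(pts[, seq_len(object@dim)] < 0) ||
        any(sweep(pts[, seq_len(object@dim), drop = FALSE], 2,
                  object@region[seq_len(object@dim)]) > 1e-9))
      return("segment endpoints must lie inside region")
  }
  TRUE
})

#' Ordered stack of regular-imaging frames
#'
#' @slot frames list of amplitude arrays, all sharing the configured grid
#'   shape, normalized to [0, 1].
#' @slot config an \linkS4class{ImagingConfig}.
#' @slot perFrameTime numeric, acquisition time per frame in seconds.
#' @slot events data.frame of the generating absorber events (may be empty
#'   when the series was read from disk).
#' @export
setClass("FrameSeries",
  representation(frames = "list", config = "ImagingConfig",
                 perFrameTime = "numeric", events = "data.frame"))

setValidity("FrameSeries", function(object) {
  if (length(object@frames) < 1) return("a FrameSeries needs at least 1 frame")
  gs <- object@config@gridShape
  for (f in object@frames) {
    if (!identical(dim(f), as.integer(gs)))
      return("all frames must share the configured grid shape")
    if (min(f) < 0 || max(f) > 1 + 1e-9)
      return("frame amplitudes must be normalized to [0, 1]")
  }
  if (object@perFrameTime <= 0) return("perFrameTime must be positive")
  TRUE
})

#' Sub-pixel absorber localizations
#'
#' Positions are in source-grid units (0-based, pixel centers at integers), so
#' a position of 10.3 lies 0.3 pixels past the center of the 11th pixel.
#'
#' @slot events data.frame with columns \code{x,y[,z],amplitude,frame_index}.
#' @slot gridShape integer vector, shape of the source grid.
#' @slot superresFactor integer >= 1, refinement factor of the target grid.
#' @export
setClass("LocalizationEvents",
  representation(events = "data.frame", gridShape = "integer",
                 superresFactor = "integer"))

setValidity("LocalizationEvents", function(object) {
  nd <- length(object@gridShape)
  ax <- c("x", "y", "z")[seq_len(nd)]
  e <- object@events
  if (!all(c(ax, "amplitude", "frame_index") %in% names(e)))
    return("events must have per-axis position, amplitude and frame_index")
  if (object@superresFactor < 1L) return("superresFactor must be >= 1")
  if (nrow(e) > 0) {
    if (any(e$amplitude <= 0)) return("event amplitudes must be > 0")
    for (i in seq_len(nd))
      if (any(e[[ax[i]]] < -0.5 | e[[ax[i]]] > object@gridShape[i] - 0.5))
        return("event positions must lie within grid bounds")
  }
  TRUE
})

#' Rasterized localization image
#'
#' Superposition of localization events on a (possibly finer) grid,
#' normalized to [0, 1].  \code{kUsed} counts the contributing frames (or
#' droplets, for event-wise selection) out of \code{nTotal} available.
#'
#' @slot data amplitude array on the superresolution grid.
#' @slot kUsed integer, number of contributing frames or droplets.
#' @slot nTotal integer, total available frames or droplets.
#' @slot superresFactor integer >= 1.
#' @export
setClass("LocalizationImage",
  representation(data = "array", kUsed = "integer", nTotal = "integer",
                 superresFactor = "integer"))

setValidity("LocalizationImage", function(object) {
  if (object@kUsed > object@nTotal) return("kUsed must be <= nTotal")
  if (object@superresFactor < 1L) return("superresFactor must be >= 1")
  if (length(object@data) &&
      (min(object@data) < 0 || max(object@data) > 1 + 1e-9))
    return("amplitudes must be non-negative and normalized to [0, 1]")
  TRUE
})

#' Quality-metric configuration (PSNR / SSIM / MS-SSIM)
#'
#' Defaults are the standard constants: stability terms
#' \eqn{C_1 = (0.01 R)^2}, \eqn{C_2 = (0.03 R)^2} for dynamic range R, an
#' 11-point Gaussian window with sigma 1.5, and the canonical five-scale
#' weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333).
#'
#' @slot dynamicRange numeric, value range of the compared images (default 1).
#' @slot k1,k2 numeric, SSIM stability coefficients.
#' @slot windowSize odd integer, Gaussian window width in pixels.
#' @slot windowSigma numeric, Gaussian window standard deviation in pixels.
#' @slot scales integer or NULL; NULL auto-selects the largest feasible scale
#'   count up to 5, with a notice when clamped below 5.
#' @slot weights numeric, per-scale exponents; renormalized to sum to one
#'   when the scale count is clamped.
#' @export
setClass("MetricConfig",
  representation(dynamicRange = "numeric", k1 = "numeric", k2 = "numeric",
                 windowSize = "integer", windowSigma = "numeric",
                 scales = "numericOrNULL", weights = "numeric"))

setValidity("MetricConfig", function(object) {
  if (object@dynamicRange <= 0) return("dynamicRange must be > 0")
  if (object@k1 <= 0 || object@k2 <= 0) return("k1 and k2 must be > 0")
  if (object@windowSize < 3L || object@windowSize %% 2L == 0L)
    return("windowSize must be an odd integer >= 3")
  if (object@windowSigma <= 0) return("windowSigma must be > 0")
  if (!is.null(object@scales) && object@scales < 1)
    return("scales must be >= 1")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
    return("weights must be non-negative and sum to 1")
  TRUE
})

#' Generator architecture specification
#'
#' Hyperparameters of the customized U-Net generator: a contraction path of
#' \code{levels} convolution blocks (each followed by 2x max-pooling), a
#' mirrored expansion path whose upsampling is a transposed convolution (3D)
#' or a sub-pixel (pixel-shuffle) convolution (2D), long skip connections by
#' channel-wise concatenation, short skip connections by element-wise
#' summation of a stride-1 max-pooled copy of each block input, and one
#' output convolution with a sigmoid onto [0, 1].  The 3D variant takes two
#' input channels (sparse localization + regular volume) and keeps feature
#' normalization and spatial dropout; the 2D variant takes the sparse
#' localization image alone and omits both, as they degrade planar results.
#'
#' @slot dim integer, 2 or 3.
#' @slot inChannels integer, generator input channels.
#' @slot baseWidth integer, channel width of the first level (doubling per
#'   level up to \code{widthCap}).
#' @slot widthCap integer, maximum channel width.
#' @slot levels integer, number of down/up stages.
#' @slot convsPerBlock integer, feature convolutions per block.
#' @slot upsample character, "transposed" or "pixel_shuffle".
#' @slot batchnorm logical, per-channel feature normalization in blocks.
#' @slot dropout numeric, spatial (whole-channel) dropout rate.
#' @slot kernel integer, feature convolution kernel width.
#' @export
setClass("GeneratorSpec",
  representation(dim = "integer", inChannels = "integer", baseWidth = "integer",
                 widthCap = "integer", levels = "integer",
                 convsPerBlock = "integer", upsample = "character",
                 batchnorm = "logical", dropout = "numeric",
                 kernel = "integer"))

setValidity("GeneratorSpec", function(object) {
  if (!object@dim %in% c(2L, 3L)) return("dim must be 2 or 3")
  if (object@dim == 3L && object@upsample != "transposed")
    return("3D generators use transposed-convolution upsampling")
  if (object@dim == 2L) {
    if (object@upsample != "pixel_shuffle")
      return("2D generators use pixel-shuffle upsampling")
    if (object@batchnorm || object@dropout > 0)
      return("2D generators omit normalization and spatial dropout")
  }
  if (object@levels < 1L || object@convsPerBlock < 1L)
    return("levels and convsPerBlock must be >= 1")
  if (object@baseWidth < 1L || object@widthCap < object@baseWidth)
    return("baseWidth must be >= 1 and <= widthCap")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@kernel %% 2L == 0L) return("kernel must be odd")
  TRUE
})

#' Discriminator architecture specification
#'
#' Five convolutional layers in series: four stride-2 blocks with leaky
#' rectified linear activations followed by one output convolution with a
#' sigmoid, producing a patch-wise probability map in (0, 1).
#'
#' @slot dim integer, 2 or 3.
#' @slot inChannels integer, input channels (1).
#' @slot baseWidth integer, width of the first block (doubling per block).
#' @slot leakySlope numeric, negative slope of the leaky rectifier.
#' @slot kernel odd integer, convolution kernel width.
#' @export
setClass("DiscriminatorSpec",
  representation(dim = "integer", inChannels = "integer", baseWidth = "integer",
                 leakySlope = "numeric", kernel = "integer"))

setValidity("DiscriminatorSpec", function(object) {
  if (!object@dim %in% c(2L, 3L)) return("dim must be 2 or 3")
  if (object@baseWidth < 1L) return("baseWidth must be >= 1")
  if (object@leakySlope <= 0 || object@leakySlope >= 1)
    return("leakySlope must be in (0, 1)")
  if (object@kernel %% 2L == 0L) return("kernel must be odd")
  TRUE
})

#' A built network (generator or discriminator)
#'
#' Holds the architecture plan and the trainable parameters.  Use
#' \code{\link{networkForward}} to run it and
#' \code{\link{countParameters}} for the exact trainable-scalar count.
#'
#' @slot spec the originating \linkS4class{GeneratorSpec} or
#'   \linkS4class{DiscriminatorSpec}.
#' @slot plan list of layer descriptors.
#' @slot params named list of numeric parameter arrays.
#' @slot role character, "generator" or "discriminator".
#' @export
setClass("PANetwork",
  representation(spec = "ANY", plan = "list", params = "list",
                 role = "character"))

#' Training sample: generator input paired with its dense target
#'
#' \code{x} carries a trailing channel axis (two channels for the 3D network:
#' sparse localization + regular volume; one for 2D); \code{y} is the dense
#' localization target on the same spatial grid.
#'
#' @slot x numeric array, spatial axes then channels.
#' @slot y numeric array, spatial axes only.
#' @export
setClass("PairedSample", representation(x = "array", y = "array"))

setValidity("PairedSample", function(object) {
  dx <- dim(object@x); dy <- dim(object@y)
  if (length(dx) != length(dy) + 1)
    return("x must have one trailing channel axis over y's spatial axes")
  if (!identical(dx[-length(dx)], dy))
    return("x and y must share spatial dimensions")
  if (min(object@x) < -1e-9 || max(object@x) > 1 + 1e-9 ||
      min(object@y) < -1e-9 || max(object@y) > 1 + 1e-9)
    return("x and y must be normalized to [0, 1]")
  TRUE
})

#' Named split of paired samples with regeneration provenance
#'
#' @slot splitName character: "train", "val" or "test".
#' @slot samples list of \linkS4class{PairedSample}.
#' @slot provenance list recording the seed and generation parameters that
#'   suffice to regenerate the split bit-identically.
#' @export
setClass("DatasetBundle",
  representation(splitName = "character", samples = "list",
                 provenance = "list"))

#' Training configuration
#'
#' @slot mode character: "orpam3d" (MAE + adversarial volumetric loss),
#'   "pretrain2d" (MAE + MS-SSIM, no adversary) or "pact2d"
#'   (MAE + MS-SSIM + adversarial).
#' @slot epochs integer, training epochs (full-scale default 200; pass a
#'   small value for desk-scale runs).
#' @slot learningRate,beta1,beta2 Adam hyperparameters.
#' @slot l2 numeric, L2 regularization coefficient.
#' @slot maxGradNorm numeric, global gradient-norm clip (Inf disables).
#' @slot batchSize integer.
#' @slot cropSize integer vector or NULL, random-crop size for augmentation.
#' @slot flipProb numeric, per-axis x/y flip probability.
#' @slot seed integer, master seed for initialization, shuffling and
#'   augmentation.
#' @slot metricConfig \linkS4class{MetricConfig} used for the MS-SSIM loss
#'   term and validation checkpointing.
#' @export
setClass("TrainConfig",
  representation(mode = "character", epochs = "integer",
                 learningRate = "numeric", beta1 = "numeric", beta2 = "numeric",
                 l2 = "numeric", maxGradNorm = "numeric", batchSize = "integer",
                 cropSize = "numericOrNULL", flipProb = "numeric",
                 seed = "integer", metricConfig = "MetricConfig"))

setValidity("TrainConfig", function(object) {
  if (!object@mode %in% c("orpam3d", "pretrain2d", "pact2d"))
    return("mode must be one of orpam3d, pretrain2d, pact2d")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@flipProb < 0 || object@flipProb > 1)
    return("flipProb must be in [0, 1]")
  if (object@learningRate <= 0 || object@l2 < 0)
    return("learningRate must be > 0 and l2 >= 0")
  TRUE
})
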