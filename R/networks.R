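#' @include autodiff.R
NULL

#' Construct a generator architecture specification
#'
#' Defaults realize the full-size networks: four down/up levels with two
#' feature convolutions per block plus one output convolution (17
#' convolutional layers in that accounting, upsampling operators counted
#' separately), channel widths doubling from \code{baseWidth} up to
#' \code{widthCap}.  The default 3D generator (2 input channels, base 64,
#' cap 512) carries about 45.7 million trainable parameters; the default 2D
#' generator (1 input channel, base 120) about 104 million.
#'
#' @param dim 2 or 3.
#' @param inChannels generator input channels; defaults to 2 in 3D (sparse
#'   localization + regular volume) and 1 in 2D (sparse localization image).
#' @param baseWidth first-level channel width; defaults 64 (3D) / 120 (2D).
#' @param widthCap maximum channel width (default 512 in 3D, uncapped in 2D).
#' @param levels down/up stages (default 4).
#' @param convsPerBlock feature convolutions per block (default 2).
#' @param batchnorm,dropout 3D-only feature normalization and spatial
#'   dropout; forced off in 2D where they degrade results.
#' @param kernel feature convolution width (default 3).
#' @return a \linkS4class{GeneratorSpec}.
#' @export
GeneratorSpec <- function(dim = 3L, inChannels = NULL, baseWidth = NULL,
                          widthCap = NULL, levels = 4L, convsPerBlock = 2L,
                          batchnorm = NULL, dropout = NULL, kernel = 3L) {
  dim <- as.integer(dim)
  if (is.null(inChannels)) inChannels <- if (dim == 3L) 2L else 1L
  if (is.null(baseWidth)) baseWidth <- if (dim == 3L) 64L else 120L
  if (is.null(widthCap)) widthCap <- if (dim == 3L) 512L else 8192L
  if (is.null(batchnorm)) batchnorm <- dim == 3L
  if (is.null(dropout)) dropout <- if (dim == 3L) 0.2 else 0
  new("GeneratorSpec", dim = dim, inChannels = as.integer(inChannels),
      baseWidth = as.integer(baseWidth), widthCap = as.integer(widthCap),
      levels = as.integer(levels), convsPerBlock = as.integer(convsPerBlock),
      upsample = if (dim == 3L) "transposed" else "pixel_shuffle",
      batchnorm = batchnorm, dropout = dropout, kernel = as.integer(kernel))
}

#' Construct a discriminator architecture specification
#'
#' @param dim 2 or 3.
#' @param inChannels input channels (default 1).
#' @param baseWidth width of the first block, doubling per block; default 64,
#'   giving about 4.7 million parameters in 3D and 1.6 million in 2D.
#' @param leakySlope leaky-rectifier negative slope (default 0.2).
#' @param kernel convolution width (default 3).
#' @return a \linkS4class{DiscriminatorSpec}.
#' @export
DiscriminatorSpec <- function(dim = 3L, inChannels = 1L, baseWidth = 64L,
                              leakySlope = 0.2, kernel = 3L) {
  new("DiscriminatorSpec", dim = as.integer(dim),
      inChannels = as.integer(inChannels), baseWidth = as.integer(baseWidth),
      leakySlope = leakySlope, kernel = as.integer(kernel))
}

genWidths <- function(spec)
  pmin(spec@baseWidth * 2^(seq_len(spec@levels) - 1L), spec@widthCap)

# Enumerate parameterized layers: the single source of truth for the builder
# and for analytic parameter counting.  Types: "conv" (feature convolution,
# counted in the 17-layer accounting), "upconv" (upsampling pre-convolution,
# counted separately), "norm" (per-channel gain/bias).
genLayerPlan <- function(spec) {
  w <- genWidths(spec)
  L <- spec@levels
  k <- spec@kernel
  nd <- spec@dim
  plan <- list()
  addConv <- function(name, cin, cout, kernel, type = "conv") {
    plan[[length(plan) + 1L]] <<- list(type = type, name = name,
                                       cin = cin, cout = cout, kernel = kernel)
    if (spec@batchnorm && type == "conv" && name != "out")
      plan[[length(plan) + 1L]] <<- list(type = "norm",
                                         name = paste0(name, ".norm"), c = cout)
  }
  # the closing convolution of each residual block is zero-initialized so
  # every block starts as its max-pool shortcut (He normal elsewhere); this
  # keeps feature magnitudes bounded through the skip-heavy topology
  zero <- function(j) spec@convsPerBlock > 1L && j == spec@convsPerBlock
  for (i in seq_len(L)) {
    cin <- if (i == 1L) spec@inChannels else w[i - 1L]
    for (j in seq_len(spec@convsPerBlock)) {
      addConv(sprintf("enc%d.conv%d", i, j), if (j == 1L) cin else w[i], w[i], k)
      plan[[length(plan) - spec@batchnorm]]$zeroInit <- zero(j)
    }
  }
  cur <- w[L]
  for (i in rev(seq_len(L))) {
    upk <- if (spec@upsample == "transposed") 1L else 3L
    addConv(sprintf("up%d", i), cur, w[i] * 2L^nd, upk, type = "upconv")
    for (j in seq_len(spec@convsPerBlock)) {
      cin <- if (j == 1L) 2L * w[i] else w[i]
      addConv(sprintf("dec%d.conv%d", i, j), cin, w[i], k)
      plan[[length(plan) - spec@batchnorm]]$zeroInit <- zero(j)
    }
    cur <- w[i]
  }
  addConv("out", w[1L], 1L, k)
  plan
}

discLayerPlan <- function(spec) {
  k <- spec@kernel
  plan <- list()
  cin <- spec@inChannels
  for (b in seq_len(4L)) {
    cout <- spec@baseWidth * 2L^(b - 1L)
    plan[[length(plan) + 1L]] <- list(type = "conv",
                                      name = sprintf("block%d", b),
                                      cin = cin, cout = cout, kernel = k,
                                      stride = 2L)
    cin <- cout
  }
  plan[[length(plan) + 1L]] <- list(type = "conv", name = "out",
                                    cin = cin, cout = 1L, kernel = k,
                                    stride = 1L)
  plan
}

layerParamCount <- function(l, nd) {
  if (l$type == "norm") return(2 * l$c)
  l$cout * (l$kernel^nd * l$cin + 1)
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "PANetwork", function(object)
  sum(vapply(object@params, length, numeric(1))))

#' @rdname countParameters
#' @export
setMethod("countParameters", "GeneratorSpec", function(object)
  sum(vapply(genLayerPlan(object), layerParamCount, numeric(1), nd = object@dim)))

#' @rdname countParameters
#' @export
setMethod("countParameters", "DiscriminatorSpec", function(object)
  sum(vapply(discLayerPlan(object), layerParamCount, numeric(1), nd = object@dim)))

heInitParams <- function(plan, nd, seed = NULL) {
  doInit <- function() {
    params <- list()
    for (l in plan) {
      if (l$type == "norm") {
        params[[paste0(l$name, ".gain")]] <- rep(1, l$c)
        params[[paste0(l$name, ".bias")]] <- rep(0, l$c)
      } else {
        fanIn <- l$kernel^nd * l$cin
        params[[paste0(l$name, ".w")]] <- if (isTRUE(l$zeroInit))
          matrix(0, l$cout, fanIn)
        else
          matrix(stats::rnorm(l$cout * fanIn, 0, sqrt(2 / fanIn)), l$cout, fanIn)
        params[[paste0(l$name, ".b")]] <- rep(0, l$cout)
      }
    }
    params
  }
  if (is.null(seed)) doInit() else withSeed(seed, doInit())
}

#' Build a U-Net generator
#'
#' Instantiates the generator of the sparse-to-dense localization mapping:
#' see \linkS4class{GeneratorSpec} for the architecture.  Weights are
#' He-normal initialized, except the closing convolution of each residual
#' block, which starts at zero so the block initially passes its max-pool
#' shortcut through -- a standard residual-network scale guard that keeps
#' activations bounded at any depth.  The returned network is run with
#' \code{\link{networkForward}} and trained with \code{\link{fitGAN}}.
#'
#' @param spec a \linkS4class{GeneratorSpec}.
#' @param seed integer initialization seed (identical seeds give identical
#'   weights); NULL draws from the current RNG stream.
#' @return a \linkS4class{PANetwork}.
#' @examples
#' g <- buildGenerator(GeneratorSpec(dim = 2, baseWidth = 4, levels = 2), seed = 1)
#' dim(networkForward(g, array(runif(16 * 16), c(16, 16, 1))))
#' @export
buildGenerator <- function(spec, seed = NULL) {
  validObject(spec)
  plan <- genLayerPlan(spec)
  new("PANetwork", spec = spec, plan = plan,
      params = heInitParams(plan, spec@dim, seed), role = "generator")
}

#' Build a patch discriminator
#'
#' Five convolutional layers in series (four stride-2 leaky-rectifier blocks
#' and a sigmoid output convolution) mapping an image or volume to a
#' patch-wise probability map in (0, 1).
#'
#' @param spec a \linkS4class{DiscriminatorSpec}.
#' @param seed integer initialization seed.
#' @return a \linkS4class{PANetwork}.
#' @export
buildDiscriminator <- function(spec, seed = NULL) {
  validObject(spec)
  plan <- discLayerPlan(spec)
  new("PANetwork", spec = spec, plan = plan,
      params = heInitParams(plan, spec@dim, seed), role = "discriminator")
}

# wrap every parameter as a gradient-requiring leaf
paramNodes <- function(tape, params)
  lapply(params, function(p) adLeaf(tape, p, requires = TRUE))

convOf <- function(tape, x, pn, name, kernel, nd, stride = 1L) {
  pad <- (kernel - 1L) %/% 2L
  adConv(x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
         rep(kernel, nd), rep(stride, nd), rep(pad, nd), tape)
}

# generator forward pass on the tape; `train` enables spatial dropout
genForward <- function(tape, net, x, pn, train = FALSE) {
  spec <- net@spec
  nd <- spec@dim
  L <- spec@levels
  k <- spec@kernel
  w <- genWidths(spec)
  dx <- dim(x$value)
  sdim <- dx[-length(dx)]
  if (any(sdim %% 2L^L != 0L))
    stop(sprintf(
      "invalid argument: input spatial size %s must be divisible by 2^levels = %d",
      paste(sdim, collapse = "x"), 2L^L))

  block <- function(x, prefix, width) {
    # short skip: stride-1 max-pooled copy of the block input, summed in
    h <- x
    for (j in seq_len(spec@convsPerBlock)) {
      h <- convOf(tape, h, pn, sprintf("%s.conv%d", prefix, j), k, nd)
      if (spec@batchnorm) {
        nn <- sprintf("%s.conv%d.norm", prefix, j)
        h <- adInstanceNorm(h, pn[[paste0(nn, ".gain")]],
                            pn[[paste0(nn, ".bias")]], tape)
      }
      h <- adLeakyRelu(h, 0.2, tape)
    }
    short <- adFitChannels(adMaxPool(x, 3L, 1L, 1L, tape), width, tape)
    h <- adAdd(h, short, tape)
    if (train && spec@dropout > 0) {
      keep <- stats::runif(width) >= spec@dropout
      h <- adChannelMask(h, as.numeric(keep) / (1 - spec@dropout), tape)
    }
    h
  }

  skips <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    h <- block(h, sprintf("enc%d", i), w[i])
    skips[[i]] <- h
    h <- adMaxPool(h, 2L, 2L, 0L, tape)
  }
  for (i in rev(seq_len(L))) {
    h <- convOf(tape, h, pn, sprintf("up%d", i),
                if (spec@upsample == "transposed") 1L else 3L, nd)
    h <- adPixelShuffle(h, tape)
    h <- adConcatC(h, skips[[i]], tape)
    h <- block(h, sprintf("dec%d", i), w[i])
  }
  adSigmoid(convOf(tape, h, pn, "out", k, nd), tape)
}

discForward <- function(tape, net, x, pn) {
  spec <- net@spec
  nd <- spec@dim
  h <- x
  for (b in seq_len(4L)) {
    h <- convOf(tape, h, pn, sprintf("block%d", b), spec@kernel, nd, stride = 2L)
    h <- adLeakyRelu(h, spec@leakySlope, tape)
  }
  adSigmoid(convOf(tape, h, pn, "out", spec@kernel, nd), tape)
}

#' Run a built network on an input array
#'
#' For a generator, the input carries a trailing channel axis matching the
#' spec (e.g. \code{c(64, 64, 64, 2)} for the default 3D network) and the
#' output drops it; spatial sizes must be divisible by \code{2^levels}.  For
#' a discriminator, the input is a single-channel image/volume (the channel
#' axis may be omitted) and the output is the patch probability map.
#'
#' @param net a \linkS4class{PANetwork}.
#' @param x numeric input array.
#' @param train logical; enables spatial dropout (generator only).
#' @return numeric output array.
#' @export
networkForward <- function(net, x, train = FALSE) {
  tape <- newTape()
  nd <- net@spec@dim
  if (length(dim(x)) == nd) dim(x) <- c(dim(x), 1L)
  xn <- adLeaf(tape, x)
  pn <- paramNodes(tape, net@params)
  out <- if (net@role == "generator") genForward(tape, net, xn, pn, train)
         else discForward(tape, net, xn, pn)
  v <- out$value
  dmv <- dim(v)
  if (dmv[length(dmv)] == 1L) dim(v) <- dmv[-length(dmv)]
  v
}

#' Pixel-shuffle (sub-pixel) upsampling by a factor of 2
#'
#' Rearranges \code{2^d * C} channels into C channels at twice the spatial
#' size in every axis -- an exact permutation with no arithmetic, used in the
#' 2D generator's expansion path because transposed convolutions produce
#' checkerboard artifacts there.  In 0-based channel-first notation,
#' \code{out[c, 2i+di, 2j+dj] = in[c*4 + 2*di + dj, i, j]}.
#'
#' @param x array with spatial axes first and channels last.
#' @return upsampled array.
#' @export
pixelShuffleUpsample <- function(x) shuffleValue(x)

#' Inverse of \code{\link{pixelShuffleUpsample}} (space-to-depth)
#' @param x array with spatial axes first and channels last.
#' @return downsampled array with expanded channels.
#' @export
spaceToDepth <- function(x) shuffleValue(x, inverse = TRUE)
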