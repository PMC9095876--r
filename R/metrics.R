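#' @include AllClasses.R localization.R
NULL

#' Construct a metric configuration
#'
#' @param dynamicRange value range of the images (default 1 for normalized
#'   amplitudes).
#' @param k1,k2 SSIM stability coefficients; the stability constants are
#'   \code{C1 = (k1 * dynamicRange)^2} and \code{C2 = (k2 * dynamicRange)^2}.
#' @param windowSize odd Gaussian window width (default 11).
#' @param windowSigma Gaussian window sigma (default 1.5).
#' @param scales scale count for MS-SSIM, or NULL to auto-select the largest
#'   feasible count up to 5.
#' @param weights per-scale exponents (default the canonical five weights).
#' @return a \linkS4class{MetricConfig}.
#' @export
MetricConfig <- function(dynamicRange = 1, k1 = 0.01, k2 = 0.03,
                         windowSize = 11L, windowSigma = 1.5,
                         scales = NULL,
                         weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  weights <- weights / sum(weights)
  new("MetricConfig", dynamicRange = dynamicRange, k1 = k1, k2 = k2,
      windowSize = as.integer(windowSize), windowSigma = windowSigma,
      scales = if (is.null(scales)) NULL else as.numeric(scales),
      weights = weights)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(R^2 / \mathrm{MSE})} in decibels, dimension-agnostic.
#' Identical inputs have zero MSE; the returned value is then \code{Inf} with
#' attribute \code{zeroMSE = TRUE} as an explicit sentinel.
#'
#' @param a,b arrays of identical shape with values in [0, dynamicRange].
#' @param config a \linkS4class{MetricConfig}.
#' @return decibels (numeric scalar).
#' @examples
#' psnr(matrix(0, 4, 4), matrix(0.1, 4, 4)) # MSE 0.01 -> 20 dB
#' @export
psnr <- function(a, b, config = MetricConfig()) {
  if (!identical(dim(a), dim(b)))
    stop("invalid argument: a and b must have identical shape")
  mse <- mean((a - b)^2)
  if (mse == 0) {
    out <- Inf
    attr(out, "zeroMSE") <- TRUE
    return(out)
  }
  10 * log10(config@dynamicRange^2 / mse)
}

# separable Gaussian window filtering (zero padding; callers crop the
# half-window border so boundary handling never reaches reported values)
winFilter <- function(x, win, sigma) {
  half <- (win - 1L) %/% 2L
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- x
  for (d in seq_len(length(dim(x)))) out <- convAlongAxisZero(out, k, d)
  out
}

convAlongAxisZero <- function(x, k, d) {
  dm <- dim(x)
  nd <- length(dm)
  perm <- c(d, seq_len(nd)[-d])
  m <- matrix(aperm(x, perm), nrow = dm[d])
  half <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow = dm[d], ncol = ncol(m))
  n <- dm[d]
  for (j in seq_along(k)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, dm[perm]), order(perm))
}

cropBorder <- function(x, half) {
  dm <- dim(x)
  idx <- lapply(dm, function(n) (half + 1L):(n - half))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# luminance and contrast-structure means of the SSIM decomposition
ssimComponents <- function(a, b, config) {
  win <- config@windowSize
  sigma <- config@windowSigma
  if (any(dim(a) < win))
    stop("invalid argument: window larger than image")
  C1 <- (config@k1 * config@dynamicRange)^2
  C2 <- (config@k2 * config@dynamicRange)^2
  half <- (win - 1L) %/% 2L
  ua <- winFilter(a, win, sigma); ub <- winFilter(b, win, sigma)
  uaa <- winFilter(a * a, win, sigma); ubb <- winFilter(b * b, win, sigma)
  uab <- winFilter(a * b, win, sigma)
  ua <- cropBorder(ua, half); ub <- cropBorder(ub, half)
  va <- cropBorder(uaa, half) - ua^2
  vb <- cropBorder(ubb, half) - ub^2
  vab <- cropBorder(uab, half) - ua * ub
  lum <- (2 * ua * ub + C1) / (ua^2 + ub^2 + C1)
  cs <- (2 * vab + C2) / (va + vb + C2)
  list(luminance = mean(lum), cs = mean(cs), ssim = mean(lum * cs))
}

#' Structural similarity index
#'
#' Mean local SSIM with Gaussian weighting over 2D or 3D inputs.  Local
#' statistics are computed in a Gaussian window and averaged over the region
#' where the window fits entirely inside the image.
#'
#' @inheritParams psnr
#' @return SSIM score in (-1, 1]; exactly 1 for identical inputs.
#' @export
ssim <- function(a, b, config = MetricConfig()) {
  if (!identical(dim(a), dim(b)))
    stop("invalid argument: a and b must have identical shape")
  a <- dropSingletonDims(a)
  b <- dropSingletonDims(b)
  ssimComponents(a, b, config)$ssim
}

# singleton axes (e.g. a depth-1 volume) carry no structure: drop them so the
# 3D path reduces exactly to the 2D one
dropSingletonDims <- function(x) {
  dm <- dim(x)
  if (length(dm) > 2L && any(dm == 1L)) {
    keep <- dm[dm > 1L]
    if (length(keep) < 2L) keep <- c(keep, rep(1L, 2L - length(keep)))
    dim(x) <- keep
  }
  x
}

# largest scale count such that the window fits after dyadic halvings
maxFeasibleScales <- function(dm, win) {
  m <- 0L
  while (all(floor(dm / 2^m) >= win)) m <- m + 1L
  m
}

# 2x average pooling; a trailing odd sample is dropped
avgPoolHalf <- function(x) {
  dm <- dim(x)
  nd <- length(dm)
  for (d in seq_len(nd)) {
    n2 <- floor(dim(x)[d] / 2)
    i1 <- seq_len(n2) * 2L - 1L
    idxA <- lapply(seq_len(nd), function(dd)
      if (dd == d) i1 else seq_len(dim(x)[dd]))
    idxB <- idxA; idxB[[d]] <- i1 + 1L
    x <- (do.call(`[`, c(list(x), idxA, list(drop = FALSE))) +
          do.call(`[`, c(list(x), idxB, list(drop = FALSE)))) / 2
  }
  x
}

# resolve requested scale count against image size; errors on explicit
# infeasible requests, clamps (with a notice) when auto-selecting
resolveScales <- function(dm, config) {
  feas <- maxFeasibleScales(dm, config@windowSize)
  if (feas < 1L)
    stop("invalid argument: window larger than image at every scale")
  want <- if (is.null(config@scales)) length(config@weights)
          else as.integer(config@scales)
  if (!is.null(config@scales) && want > feas)
    stop(sprintf(
      "invalid argument: %d scales requested but at most %d feasible for size %s with an %d-point window",
      want, feas, paste(dm, collapse = "x"), config@windowSize))
  m <- min(want, feas)
  if (is.null(config@scales) && m < want)
    message(sprintf("ms_ssim: scale count clamped to %d for size %s", m,
                    paste(dm, collapse = "x")))
  w <- config@weights[seq_len(m)]
  list(m = m, weights = w / sum(w))
}

#' Multiscale structural similarity
#'
#' The dyadic-pyramid SSIM aggregate: contrast-structure similarity is
#' measured at every scale, full SSIM (with luminance) at the coarsest, and
#' the terms are combined as a weighted geometric mean.  Downsampling between
#' scales is 2x average pooling.  With a single scale and unit weight the
#' score equals \code{\link{ssim}}.
#'
#' @inheritParams psnr
#' @return MS-SSIM score in (0, 1] for non-negative inputs; exactly 1 for
#'   identical inputs.
#' @export
msSSIM <- function(a, b, config = MetricConfig()) {
  if (!identical(dim(a), dim(b)))
    stop("invalid argument: a and b must have identical shape")
  a <- dropSingletonDims(a)
  b <- dropSingletonDims(b)
  sc <- resolveScales(dim(a), config)
  m <- sc$m; w <- sc$weights
  score <- 1
  for (j in seq_len(m)) {
    comp <- ssimComponents(a, b, config)
    term <- if (j == m) comp$ssim else comp$cs
    score <- score * max(term, 1e-8)^w[j]
    if (j < m) { a <- avgPoolHalf(a); b <- avgPoolHalf(b) }
  }
  score
}

#' Evaluate prediction quality against targets
#'
#' Convenience wrapper computing PSNR and MS-SSIM for pairs of images or
#' volumes, as used for network evaluation sweeps.
#'
#' @param pred,target single arrays or lists of arrays.
#' @param config a \linkS4class{MetricConfig}.
#' @return data.frame with columns sample_id, psnr_db, ms_ssim.
#' @export
evaluatePairs <- function(pred, target, config = MetricConfig()) {
  if (!is.list(pred)) { pred <- list(pred); target <- list(target) }
  stopifnot(length(pred) == length(target))
  do.call(rbind, lapply(seq_along(pred), function(i)
    data.frame(sample_id = i,
               psnr_db = as.numeric(psnr(pred[[i]], target[[i]], config)),
               ms_ssim = msSSIM(pred[[i]], target[[i]], config))))
}
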