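#' @include AllClasses.R
NULL

# save/seed/restore the RNG around `expr`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# difference-of-Gaussians band-pass on a 2D/3D array (sigmas in pixels)
dogFilter <- function(x, sigma1 = 1, sigma2 = 2) {
  gaussSmooth(x, sigma1) - gaussSmooth(x, sigma2)
}

# separable Gaussian smoothing via the compiled convolution kernel
gaussSmooth <- function(x, sigma) {
  nd <- length(dim(x))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- x
  for (d in seq_len(nd)) out <- convAlongAxis(out, k, d)
  out
}

# 1D convolution along axis `d` with replicate ("nearest") boundary handling
convAlongAxis <- function(x, k, d) {
  dm <- dim(x)
  nd <- length(dm)
  perm <- c(d, seq_len(nd)[-d])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = dm[d])
  half <- (length(k) - 1L) / 2L
  idx <- function(i) pmin(pmax(i, 1L), dm[d])
  out <- matrix(0, nrow = dm[d], ncol = ncol(m))
  for (j in seq_along(k)) {
    off <- j - 1L - half
    out <- out + k[j] * m[idx(seq_len(dm[d]) + off), , drop = FALSE]
  }
  aperm(array(out, dm[perm]), order(perm))
}

# logical array of strict local maxima over the full neighborhood
# (8-connected in 2D, 26-connected in 3D); ties within flat plateaus are
# resolved toward the lexicographically smallest index via >= on forward shifts
localMaxima <- function(x) {
  dm <- dim(x)
  nd <- length(dm)
  shifts <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  res <- array(TRUE, dm)
  pad <- function(i, n, off) {
    j <- i + off
    j[j < 1L | j > n] <- NA
    j
  }
  for (r in seq_len(nrow(shifts))) {
    off <- shifts[r, ]
    idx <- lapply(seq_len(nd), function(d) pad(seq_len(dm[d]), dm[d], off[d]))
    shifted <- array(NA_real_, dm)
    src <- lapply(seq_len(nd), function(d) which(!is.na(idx[[d]])))
    dstIdx <- src
    srcIdx <- lapply(seq_len(nd), function(d) idx[[d]][src[[d]]])
    shifted <- do.call(`[<-`, c(list(shifted), dstIdx,
                                list(do.call(`[`, c(list(x), srcIdx)))))
    forward <- (off[which(off != 0)[1]] > 0)
    cmp <- if (forward) x >= shifted else x > shifted
    cmp[is.na(cmp)] <- TRUE
    res <- res & cmp
  }
  res
}

#' Localize point absorbers in a regular frame
#'
#' The stand-in localization operator: a difference-of-Gaussians band-pass
#' suppresses background and noise, strict local maxima above an amplitude
#' threshold seed candidate detections, candidates closer than
#' \code{minSeparation} pixels are pruned greedily by descending amplitude,
#' and each survivor is refined to sub-pixel precision by the
#' intensity-weighted centroid of the raw frame within an odd
#' \code{window}-pixel box.
#'
#' @param frame 2D or 3D amplitude array in [0, 1].
#' @param threshold amplitude threshold in (0, 1), applied to the raw frame
#'   value at the candidate peak.
#' @param minSeparation minimum distance between events, pixels.
#' @param window odd centroid window width, pixels.
#' @param dogSigma two band-pass sigmas in pixels.
#' @param frameIndex 0-based frame index stored with the events.
#' @return a \linkS4class{LocalizationEvents}; empty for an all-zero frame.
#' @examples
#' cfg <- ImagingConfig(c(32, 32), pixelSize = c(5, 5), psfFWHM = c(15, 15),
#'                      noiseSD = 0)
#' fr <- renderFrame(data.frame(x = 80, y = 80, amplitude = 1), cfg)
#' localEvents(localizeFrame(fr, threshold = 0.2))
#' @export
localizeFrame <- function(frame, threshold = 0.2, minSeparation = 2,
                          window = 7L, dogSigma = c(1, 2), frameIndex = 0L) {
  if (threshold <= 0 || threshold >= 1)
    stop("invalid argument: threshold must be in (0, 1)")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("invalid argument: window must be odd")
  dm <- dim(frame)
  nd <- length(dm)
  ax <- c("x", "y", "z")[seq_len(nd)]
  emptyEv <- stats::setNames(
    data.frame(matrix(numeric(0), 0, nd + 2)), c(ax, "amplitude", "frame_index"))
  mkEvents <- function(e) new("LocalizationEvents", events = e,
                              gridShape = as.integer(dm), superresFactor = 1L)
  if (max(frame) <= 0) return(mkEvents(emptyEv))

  filt <- dogFilter(frame, dogSigma[1], dogSigma[2])
  cand <- which(localMaxima(filt) & frame >= threshold & filt > 0)
  if (!length(cand)) return(mkEvents(emptyEv))
  coords <- arrayInd(cand, dm)
  amp <- frame[cand]
  ord <- order(amp, decreasing = TRUE)
  coords <- coords[ord, , drop = FALSE]
  amp <- amp[ord]
  # greedy min-separation pruning, strongest first
  keep <- rep(TRUE, nrow(coords))
  for (i in seq_len(nrow(coords))) {
    if (!keep[i]) next
    if (i < nrow(coords)) {
      later <- (i + 1):nrow(coords)
      d2 <- rowSums((coords[later, , drop = FALSE] -
                     matrix(coords[i, ], length(later), nd, byrow = TRUE))^2)
      keep[later][d2 < minSeparation^2] <- FALSE
    }
  }
  coords <- coords[keep, , drop = FALSE]
  amp <- amp[keep]

  half <- (window - 1L) %/% 2L
  pos <- matrix(0, nrow(coords), nd)
  for (i in seq_len(nrow(coords))) {
    lo <- pmax(coords[i, ] - half, 1L)
    hi <- pmin(coords[i, ] + half, dm)
    idx <- lapply(seq_len(nd), function(d) lo[d]:hi[d])
    w <- do.call(`[`, c(list(frame), idx))
    w <- pmax(w, 0)
    tot <- sum(w)
    if (tot <= 0) { pos[i, ] <- coords[i, ] - 1; next }
    for (d in seq_len(nd)) {
      centers <- idx[[d]] - 1 # 0-based pixel coordinates
      margin <- slice_sum(w, d)
      pos[i, d] <- sum(centers * margin) / tot
    }
  }
  ev <- data.frame(pos)
  names(ev) <- ax
  ev$amplitude <- amp
  ev$frame_index <- as.integer(frameIndex)
  mkEvents(ev)
}

# marginal sums of an nd array over all axes except `d`
slice_sum <- function(w, d) {
  if (is.null(dim(w))) return(w)
  apply(w, d, sum)
}

#' Localize every frame of a series
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param ... passed to \code{\link{localizeFrame}}.
#' @return list of \linkS4class{LocalizationEvents}, one per frame, with
#'   frame indices 0..N-1.
#' @export
localizeSeries <- function(series, ...) {
  fr <- frames(series)
  lapply(seq_along(fr) - 1L, function(f)
    localizeFrame(fr[[f + 1L]], frameIndex = f, ...))
}

#' Rasterize localization events onto a superresolution grid
#'
#' Each event deposits its amplitude at the nearest pixel of a grid refined
#' by \code{factor}; mode "sum" accumulates coincident deposits (the
#' droplet-addition construction of localization PACT) while mode "max"
#' keeps the per-pixel maximum (preserving per-vessel amplitude across
#' many OR-PAM frames).  The result is normalized to [0, 1].
#'
#' @param events a \linkS4class{LocalizationEvents} or a list of them
#'   (event tables are concatenated).
#' @param factor integer superresolution factor >= 1.
#' @param mode "sum" or "max".
#' @return a \linkS4class{LocalizationImage}.
#' @export
rasterizeEvents <- function(events, factor = 1L, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1L) stop("invalid argument: factor must be >= 1")
  if (is.list(events) && !is(events, "LocalizationEvents")) {
    gs <- events[[1]]@gridShape
    e <- do.call(rbind, lapply(events, localEvents))
  } else {
    gs <- events@gridShape
    e <- localEvents(events)
  }
  nd <- length(gs)
  ax <- c("x", "y", "z")[seq_len(nd)]
  tg <- gs * factor
  img <- array(0, dim = tg)
  if (nrow(e) > 0) {
    # source position p (0-based pixel centers) maps to superres pixel
    # floor((p + 0.5) * factor), clamped to the grid
    pix <- vapply(seq_len(nd), function(d)
      pmin(pmax(floor((e[[ax[d]]] + 0.5) * factor), 0), tg[d] - 1L),
      numeric(nrow(e)))
    pix <- matrix(as.integer(pix), nrow(e), nd)
    lin <- pix[, 1] + 1L
    mult <- 1L
    for (d in seq_len(nd - 1L)) {
      mult <- mult * tg[d]
      lin <- lin + pix[, d + 1L] * mult
    }
    if (mode == "sum") {
      acc <- rowsum(e$amplitude, lin)
      img[as.integer(rownames(acc))] <- acc[, 1]
    } else {
      acc <- vapply(split(e$amplitude, lin), max, numeric(1))
      img[as.integer(names(acc))] <- acc
    }
    if (max(img) > 0) img <- img / max(img)
  }
  nfr <- length(unique(e$frame_index))
  new("LocalizationImage", data = img, kUsed = nfr, nTotal = nfr,
      superresFactor = factor)
}

#' Dense localization image from all available frames or droplets
#'
#' Superimposes every event of every frame: the full-sampling superresolution
#' reconstruction that serves as ground truth for training and evaluation.
#'
#' @param eventSets list of per-frame \linkS4class{LocalizationEvents}.
#' @param factor superresolution factor.
#' @param mode accumulation mode, "max" (OR-PAM convention) or "sum" (PACT).
#' @param unit "frame" counts contributing frames (OR-PAM); "droplet" counts
#'   individual events (PACT).
#' @return a \linkS4class{LocalizationImage} with \code{kUsed == nTotal}.
#' @export
makeDense <- function(eventSets, factor = 1L, mode = c("max", "sum"),
                      unit = c("frame", "droplet")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (length(eventSets) < 1) stop("invalid argument: need at least one frame")
  img <- rasterizeEvents(eventSets, factor = factor, mode = mode)
  n <- if (unit == "frame") length(eventSets)
       else sum(vapply(eventSets, function(s) nrow(localEvents(s)), numeric(1)))
  initialize(img, kUsed = as.integer(n), nTotal = as.integer(n))
}

#' Sparse localization image from k randomly selected frames or droplets
#'
#' Uniform selection without replacement, reproducible under \code{seed}.
#' With \code{unit = "frame"} (OR-PAM) whole localization frames are
#' selected; with \code{unit = "droplet"} (PACT) individual events are.
#'
#' @inheritParams makeDense
#' @param k number of frames/droplets to keep, 1 <= k <= N.
#' @param seed integer selection seed.
#' @return a \linkS4class{LocalizationImage} with \code{kUsed == k}.
#' @export
makeSparse <- function(eventSets, k, seed = 1L, factor = 1L,
                       mode = c("max", "sum"), unit = c("frame", "droplet")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (unit == "frame") {
    N <- length(eventSets)
    if (k < 1 || k > N) stop("invalid argument: need 1 <= k <= N frames")
    sel <- withSeed(seed, sample.int(N, k))
    img <- rasterizeEvents(eventSets[sel], factor = factor, mode = mode)
  } else {
    all <- do.call(rbind, lapply(eventSets, localEvents))
    N <- nrow(all)
    if (k < 1 || k > N) stop("invalid argument: need 1 <= k <= N droplets")
    sel <- withSeed(seed, sample.int(N, k))
    ev <- new("LocalizationEvents", events = all[sel, , drop = FALSE],
              gridShape = eventSets[[1]]@gridShape, superresFactor = 1L)
    img <- rasterizeEvents(ev, factor = factor, mode = mode)
  }
  initialize(img, kUsed = as.integer(k), nTotal = as.integer(N))
}

#' Acquisition-time reduction factor
#'
#' The fold-change in acquisition time when k frames/droplets replace the
#' N used by a dense reconstruction: e.g. 60 OR-PAM frames reduced to 5, or
#' 240,000 PACT droplets reduced to 20,000, are both 12-fold reductions.
#'
#' @param nTotal frames/droplets in the dense reconstruction.
#' @param k frames/droplets in the sparse reconstruction (>= 1).
#' @return numeric ratio nTotal / k.
#' @examples
#' acquisitionSpeedup(60, 5)
#' @export
acquisitionSpeedup <- function(nTotal, k) {
  if (k < 1) stop("invalid argument: k must be >= 1")
  nTotal / k
}

#' Maximum amplitude projection of a volume
#'
#' @param volume 3D array (x, y, z with z axial).
#' @return 2D matrix of per-(x, y) maxima over z.
#' @export
mapProject <- function(volume) {
  if (length(dim(volume)) != 3L)
    stop("invalid argument: mapProject needs a 3D volume")
  dm <- dim(volume)
  out <- volume[, , 1]
  for (z in seq_len(dm[3])[-1]) out <- pmax(out, volume[, , z])
  out
}

#' Depth-encoded projection of a volume
#'
#' @param volume 3D array.
#' @return list with \code{depth} (0-based z index of the per-(x, y) maximum;
#'   ties take the smallest z) and \code{amplitude} (the maximum itself).
#' @export
depthEncode <- function(volume) {
  if (length(dim(volume)) != 3L)
    stop("invalid argument: depthEncode needs a 3D volume")
  dm <- dim(volume)
  m <- matrix(volume, dm[1] * dm[2], dm[3])
  depth <- max.col(m, ties.method = "first") - 1L
  list(depth = matrix(depth, dm[1], dm[2]),
       amplitude = matrix(m[cbind(seq_len(nrow(m)), depth + 1L)], dm[1], dm[2]))
}
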