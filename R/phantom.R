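#' @include AllClasses.R
NULL

#' Construct an imaging configuration
#'
#' @param gridShape integer vector of pixels per axis (length 2 or 3).
#' @param pixelSize physical pixel sizes in micrometers.  Defaults: OR-PAM
#'   lateral 3.75 and 5 um with a 3 um axial pixel (3D); PACT 25 um (2D).
#' @param psfFWHM point-spread-function full widths at half maximum in
#'   micrometers.  Defaults: 5 um lateral (optical diffraction scale) and
#'   114 um axial for OR-PAM; 125 um for PACT (five regular pixels, so a
#'   5 um superresolution grid refines the pixel area 25-fold).
#' @param noiseSD additive Gaussian noise standard deviation (default 0.02).
#' @param background constant background level (default 0).
#' @return an \linkS4class{ImagingConfig}.
#' @examples
#' ImagingConfig(c(64, 64))
#' @export
ImagingConfig <- function(gridShape,
                          pixelSize = NULL, psfFWHM = NULL,
                          noiseSD = 0.02, background = 0) {
  gridShape <- as.integer(gridShape)
  nd <- length(gridShape)
  if (is.null(pixelSize))
    pixelSize <- if (nd == 3L) c(3.75, 5, 3) else c(25, 25)
  if (is.null(psfFWHM))
    psfFWHM <- if (nd == 3L) c(5, 5, 114) else c(125, 125)
  new("ImagingConfig", gridShape = gridShape, pixelSize = as.numeric(pixelSize),
      psfFWHM = as.numeric(psfFWHM), noiseSD = noiseSD, background = background)
}

#' Generate a random branching vessel tree
#'
#' Grows a tree of straight cylindrical segments inside a rectangular region:
#' one or more root segments cross the region, and each segment spawns
#' \code{bifurcation} children at its distal end with deflected directions,
#' geometrically shrinking lengths and radii.  All endpoints are clamped to
#' the region and radii shrink monotonically with depth.
#'
#' @param region physical extent per axis in micrometers (length = dim).
#' @param dim 2 or 3.
#' @param depth branching depth; 0 yields the root segment(s) only.
#' @param seed integer seed; identical seeds give identical trees.
#' @param nRoots number of root segments (default 1).
#' @param bifurcation children per segment (default 2).
#' @param rootRadius root vessel radius in micrometers (default 4\% of the
#'   smallest region axis).
#' @param radiusFactor per-depth radius shrink factor in (0, 1).
#' @param lengthFactor per-depth length shrink factor in (0, 1).
#' @return a \linkS4class{VesselTree}.
#' @examples
#' tree <- generateVesselTree(c(240, 320), dim = 2, depth = 2, seed = 1)
#' nrow(vesselSegments(tree))
#' @export
generateVesselTree <- function(region, dim = length(region), depth = 3L,
                               seed = 1L, nRoots = 1L, bifurcation = 2L,
                               rootRadius = 0.04 * min(region),
                               radiusFactor = 0.7, lengthFactor = 0.75) {
  if (any(region <= 0)) stop("invalid argument: region must be positive on each axis")
  if (depth < 0) stop("invalid argument: depth must be >= 0")
  dim <- as.integer(dim)
  stopifnot(length(region) == dim)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  clampPt <- function(p) pmin(pmax(p, 0), region)
  segs <- list()
  addSeg <- function(p0, p1, r, d, parent) {
    p0 <- clampPt(p0); p1 <- clampPt(p1)
    z0 <- if (dim == 3L) p0[3] else 0
    z1 <- if (dim == 3L) p1[3] else 0
    segs[[length(segs) + 1L]] <<- data.frame(
      x0 = p0[1], y0 = p0[2], z0 = z0, x1 = p1[1], y1 = p1[2], z1 = z1,
      radius = r, depth = d, parent = parent)
    length(segs)
  }
  grow <- function(p0, dirn, len, r, d, parent) {
    p1 <- p0 + dirn * len
    id <- addSeg(p0, p1, r, d, parent)
    p1 <- clampPt(p1)
    if (d < depth) {
      for (b in seq_len(bifurcation)) {
        ang <- stats::runif(1, 0.25, 0.9) * (if (b %% 2 == 0) 1 else -1)
        nd2 <- rotateDir(dirn, ang, dim)
        grow(p1, nd2, len * lengthFactor, r * radiusFactor, d + 1L, id)
      }
    }
  }
  for (root in seq_len(nRoots)) {
    # root spans the region along a random principal direction with jitter
    axis <- sample.int(dim, 1)
    p0 <- stats::runif(dim, 0.1, 0.9) * region
    p0[axis] <- 0.02 * region[axis]
    dirn <- stats::rnorm(dim, 0, 0.18); dirn[axis] <- 1
    dirn <- dirn / sqrt(sum(dirn^2))
    grow(p0, dirn, 0.9 * region[axis], rootRadius, 0L, NA_integer_)
  }
  segdf <- do.call(rbind, segs)
  new("VesselTree", segments = segdf, region = as.numeric(region), dim = dim)
}

# deflect a unit direction by `ang` radians within the plane (2D) or about a
# random perpendicular axis (3D)
rotateDir <- function(dirn, ang, dim) {
  if (dim == 2L) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    as.numeric(R %*% dirn)
  } else {
    perp <- stats::rnorm(3)
    perp <- perp - sum(perp * dirn) * dirn
    perp <- perp / sqrt(sum(perp^2))
    cos(ang) * dirn + sin(ang) * perp
  }
}

#' Sample flowing absorbers inside a vessel tree
#'
#' Emulates the localization targets of photoacoustic imaging -- red blood
#' cells in label-free OR-PAM, injected dye droplets in labeled PACT.  Each
#' absorber occupies a random segment (length-weighted) at a random axial
#' fraction and radial offset strictly inside the vessel, and advances along
#' its segment between consecutive frames by a step drawn uniformly in
#' [0.5, 1.5] times \code{meanSpeed}; absorbers leaving their segment respawn.
#'
#' @param tree a \linkS4class{VesselTree} with at least one segment.
#' @param absorbersPerFrame absorbers present in each frame (>= 0).
#' @param nFrames number of frames.
#' @param seed integer seed.
#' @param meanSpeed mean advance per frame in micrometers (default 10).
#' @param amplitudeRange range of per-absorber normalized amplitudes.
#' @return data.frame with columns \code{x,y,z} (micrometers),
#'   \code{amplitude} and \code{frame_index} (0-based).
#' @examples
#' tree <- generateVesselTree(c(200, 200), dim = 2, depth = 1, seed = 1)
#' ev <- sampleAbsorbers(tree, 5, 4, seed = 2)
#' table(ev$frame_index)
#' @export
sampleAbsorbers <- function(tree, absorbersPerFrame, nFrames, seed = 1L,
                            meanSpeed = 10, amplitudeRange = c(0.6, 1)) {
  s <- tree@segments
  if (nrow(s) == 0) stop("invalid argument: empty vessel tree")
  if (absorbersPerFrame < 0) stop("invalid argument: absorbersPerFrame must be >= 0")
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      amplitude = numeric(0), frame_index = integer(0))
  if (absorbersPerFrame == 0 || nFrames == 0) return(empty)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  p0 <- as.matrix(s[, c("x0", "y0", "z0")])
  p1 <- as.matrix(s[, c("x1", "y1", "z1")])
  dvec <- p1 - p0
  len <- sqrt(rowSums(dvec^2))
  ok <- len > 1e-9
  if (!any(ok)) stop("invalid argument: vessel tree has zero-length segments only")
  probs <- len * ok / sum(len * ok)

  spawn <- function(n) {
    seg <- sample.int(nrow(s), n, replace = TRUE, prob = probs)
    t0 <- stats::runif(n)
    # radial offset: uniform over the cross-section, kept strictly inside
    roff <- 0.9 * s$radius[seg] * sqrt(stats::runif(n))
    rang <- stats::runif(n, 0, 2 * pi)
    amp <- stats::runif(n, amplitudeRange[1], amplitudeRange[2])
    list(seg = seg, t = t0, roff = roff, rang = rang, amp = amp)
  }
  posOf <- function(st) {
    axial <- p0[st$seg, , drop = FALSE] + st$t * dvec[st$seg, , drop = FALSE]
    u <- dvec[st$seg, , drop = FALSE] / len[st$seg]
    n <- length(st$seg)
    if (tree@dim == 2L) {
      perp <- cbind(-u[, 2], u[, 1], 0)
      axial + st$roff * cos(st$rang) * perp
    } else {
      ref <- matrix(rep(c(0, 0, 1), each = n), n, 3)
      alt <- abs(u[, 3]) > 0.9
      ref[alt, ] <- matrix(rep(c(1, 0, 0), each = sum(alt)), sum(alt), 3)
      e1 <- ref - rowSums(ref * u) * u
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
                  u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
                  u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
      axial + st$roff * (cos(st$rang) * e1 + sin(st$rang) * e2)
    }
  }

  st <- spawn(absorbersPerFrame)
  out <- vector("list", nFrames)
  for (f in seq_len(nFrames) - 1L) {
    pos <- posOf(st)
    out[[f + 1L]] <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                amplitude = st$amp, frame_index = f)
    step <- stats::runif(absorbersPerFrame, 0.5, 1.5) * meanSpeed / len[st$seg]
    st$t <- st$t + step
    gone <- st$t > 1
    if (any(gone)) {
      re <- spawn(sum(gone))
      for (nm in names(st)) st[[nm]][gone] <- re[[nm]]
    }
  }
  do.call(rbind, out)
}

# voxel centers along one axis, micrometers (0-based voxel i at (i + 0.5) * ps)
voxelCenters <- function(n, ps) (seq_len(n) - 0.5) * ps

#' Render one regular-imaging frame from absorber events
#'
#' Forward model: each in-grid point absorber contributes a separable
#' Gaussian point-spread function scaled by its amplitude; a constant
#' background and additive Gaussian noise (drawn from the current RNG stream)
#' are added and the result is clipped to [0, 1].  Events whose position
#' falls outside the grid extent are skipped with a warning.
#'
#' @param events data.frame with micrometer positions \code{x,y[,z]} and
#'   \code{amplitude}; typically one frame's worth.
#' @param config an \linkS4class{ImagingConfig}.
#' @return amplitude array of the configured grid shape.
#' @examples
#' cfg <- ImagingConfig(c(32, 32), noiseSD = 0)
#' fr <- renderFrame(data.frame(x = 400, y = 400, amplitude = 1), cfg)
#' which(fr == max(fr), arr.ind = TRUE)
#' @export
renderFrame <- function(events, config) {
  gs <- config@gridShape
  nd <- length(gs)
  ps <- config@pixelSize
  sig <- config@psfFWHM / (2 * sqrt(2 * log(2)))
  out <- array(0, dim = gs)
  ax <- c("x", "y", "z")[seq_len(nd)]
  if (nrow(events) > 0 && !all(ax %in% names(events)))
    stop("invalid argument: events lack position columns")
  nskip <- 0L
  for (i in seq_len(nrow(events))) {
    p <- as.numeric(events[i, ax])
    if (any(p < 0 | p > gs * ps)) { nskip <- nskip + 1L; next }
    # separable Gaussian, truncated at 4 sigma per axis
    idx <- vector("list", nd)
    prof <- vector("list", nd)
    ok <- TRUE
    for (d in seq_len(nd)) {
      ctr <- voxelCenters(gs[d], ps[d])
      keep <- which(abs(ctr - p[d]) <= 4 * sig[d])
      if (!length(keep)) { ok <- FALSE; break }
      idx[[d]] <- keep
      prof[[d]] <- exp(-(ctr[keep] - p[d])^2 / (2 * sig[d]^2))
    }
    if (!ok) next
    blob <- events$amplitude[i] * Reduce(`%o%`, prof)
    if (nd == 2L) {
      out[idx[[1]], idx[[2]]] <- out[idx[[1]], idx[[2]]] + blob
    } else {
      out[idx[[1]], idx[[2]], idx[[3]]] <- out[idx[[1]], idx[[2]], idx[[3]]] + blob
    }
  }
  if (nskip > 0)
    warning(sprintf("skipped %d event(s) outside the grid extent", nskip))
  out <- out + config@background
  if (config@noiseSD > 0)
    out <- out + stats::rnorm(length(out), 0, config@noiseSD)
  array(pmin(pmax(out, 0), 1), dim = gs)
}

#' Render a full regular-imaging frame series
#'
#' Samples flowing absorbers with \code{\link{sampleAbsorbers}} and renders
#' each frame with \code{\link{renderFrame}}; noise is seeded so identical
#' seeds give voxel-identical series.
#'
#' @inheritParams sampleAbsorbers
#' @param config an \linkS4class{ImagingConfig}.
#' @param perFrameTime seconds per frame (default 0.5: a 60-frame dense
#'   acquisition then takes 30 s).
#' @return a \linkS4class{FrameSeries} carrying the generating events.
#' @examples
#' tree <- generateVesselTree(c(160, 160), dim = 2, depth = 1, seed = 1)
#' cfg <- ImagingConfig(c(32, 32), pixelSize = c(5, 5), psfFWHM = c(15, 15))
#' ser <- renderSeries(tree, nFrames = 3, absorbersPerFrame = 4, config = cfg, seed = 7)
#' totalAcquisitionTime(ser)
#' @export
renderSeries <- function(tree, nFrames, absorbersPerFrame, config,
                         perFrameTime = 0.5, seed = 1L, meanSpeed = 10) {
  if (nFrames < 1) stop("invalid argument: nFrames must be >= 1")
  ev <- sampleAbsorbers(tree, absorbersPerFrame, nFrames, seed = seed,
                        meanSpeed = meanSpeed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed + 1L)
  nskip <- 0L
  fr <- lapply(seq_len(nFrames) - 1L, function(f)
    withCallingHandlers(
      renderFrame(ev[ev$frame_index == f, , drop = FALSE], config),
      warning = function(w) {
        if (grepl("outside the grid", conditionMessage(w))) {
          n <- as.integer(sub("skipped (\\d+) event.*", "\\1",
                              conditionMessage(w)))
          nskip <<- nskip + n
          invokeRestart("muffleWarning")
        }
      }))
  if (nskip > 0)
    warning(sprintf("skipped %d event(s) outside the grid extent across the series",
                    nskip))
  new("FrameSeries", frames = fr, config = config,
      perFrameTime = perFrameTime, events = ev)
}

#' Total acquisition time of a frame series, in seconds
#' @param series a \linkS4class{FrameSeries}.
#' @return numeric seconds (frames times per-frame time).
#' @export
totalAcquisitionTime <- function(series) {
  length(series@frames) * series@perFrameTime
}

#' Vessel-occupancy ground-truth image
#'
#' Rasterizes the tree on a (possibly finer) grid: a pixel is 1 exactly when
#' its center lies within a segment radius of that segment's axis.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param gridShape target grid shape (length = tree dim).
#' @param pixelSize target pixel sizes in micrometers.
#' @return binary amplitude array.
#' @export
groundTruthImage <- function(tree, gridShape, pixelSize) {
  gs <- as.integer(gridShape)
  nd <- tree@dim
  out <- array(0, dim = gs)
  s <- tree@segments
  if (nrow(s) == 0) return(out)
  ctr <- lapply(seq_len(nd), function(d) voxelCenters(gs[d], pixelSize[d]))
  grid <- as.matrix(expand.grid(ctr))
  p0 <- as.matrix(s[, c("x0", "y0", "z0")[seq_len(nd)], drop = FALSE])
  p1 <- as.matrix(s[, c("x1", "y1", "z1")[seq_len(nd)], drop = FALSE])
  inside <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(s))) {
    d2 <- pointSegmentDist2(grid, p0[i, ], p1[i, ])
    inside <- inside | d2 <= s$radius[i]^2
  }
  array(as.numeric(inside), dim = gs)
}

# squared distance from points (rows of `pts`) to segment [a, b]
pointSegmentDist2 <- function(pts, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 < 1e-12) return(rowSums(sweep(pts, 2, a)^2))
  t <- pmin(pmax(sweep(pts, 2, a) %*% ab / L2, 0), 1)
  proj <- matrix(a, nrow(pts), length(a), byrow = TRUE) + t %*% t(ab)
  rowSums((pts - proj)^2)
}
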