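#' @include AllClasses.R
NULL

# Catmull-Rom cubic kernel (a = -0.5)
cubicKernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# dense resampling matrix (nOut x nIn) for separable bicubic interpolation
# with kernel-width antialiasing when downsampling; edge-replicate boundary
resampleWeights <- function(nIn, nOut) {
  scale <- nIn / nOut
  width <- max(1, scale)
  W <- matrix(0, nOut, nIn)
  for (o in seq_len(nOut) - 1L) {
    u <- (o + 0.5) * scale - 0.5
    lo <- floor(u - 2 * width) ; hi <- ceiling(u + 2 * width)
    taps <- lo:hi
    wts <- cubicKernel((taps - u) / width)
    keep <- wts != 0
    taps <- pmin(pmax(taps[keep], 0), nIn - 1L)
    wts <- wts[keep]
    for (j in seq_along(taps))
      W[o + 1L, taps[j] + 1L] <- W[o + 1L, taps[j] + 1L] + wts[j]
    W[o + 1L, ] <- W[o + 1L, ] / sum(wts)
  }
  W
}

applyAlongAxis <- function(x, W, d) {
  dm <- dim(x)
  nd <- length(dm)
  perm <- c(d, seq_len(nd)[-d])
  m <- matrix(aperm(x, perm), nrow = dm[d])
  out <- W %*% m
  dmo <- dm[perm]; dmo[1] <- nrow(W)
  aperm(array(out, dmo), order(perm))
}

#' Downsample a volume along the axial (z) axis
#'
#' Bicubic downsampling with antialiasing along the last axis, the
#' preprocessing that reduces 256 axial samples to 64 before network
#' training: the axial point-spread function is far coarser than the axial
#' sampling, so a 4x reduction discards no anatomical information.
#'
#' @param volume 3D array (x, y, z).
#' @param factor integer axial reduction factor (default 4); the axial size
#'   must be divisible by it.
#' @return volume with \code{dim[3] / factor} axial samples.
#' @export
downsampleAxial <- function(volume, factor = 4L) {
  dm <- dim(volume)
  if (length(dm) != 3L) stop("invalid argument: need a 3D volume")
  if (dm[3] %% factor != 0L)
    stop(sprintf("invalid argument: axial size %d not divisible by %d",
                 dm[3], factor))
  applyAlongAxis(volume, resampleWeights(dm[3], dm[3] %/% factor), 3L)
}

#' Resize a 2D image by separable bicubic resampling with antialiasing
#'
#' Downscaling only, with independent axis scaling (source and target aspect
#' ratios may differ), as used to reduce 2000 x 2400 reconstructions to
#' 896 x 1024 working images.
#'
#' @param image 2D matrix.
#' @param target integer target shape \code{c(nx, ny)}; must not exceed the
#'   source on either axis.
#' @return resized matrix.
#' @export
resize2d <- function(image, target = c(896L, 1024L)) {
  dm <- dim(image)
  if (length(dm) != 2L) stop("invalid argument: need a 2D image")
  target <- as.integer(target)
  if (any(target > dm))
    stop("invalid argument: upscaling requested; target must not exceed source")
  out <- image
  for (d in 1:2)
    if (target[d] != dim(out)[d])
      out <- applyAlongAxis(out, resampleWeights(dm[d], target[d]), d)
  out
}

#' Split paired samples into disjoint seeded subsets
#'
#' @param samples list of samples (any objects).
#' @param fractions named numeric fractions summing to 1 (names become split
#'   names); sizes use largest-remainder rounding.
#' @param seed shuffle seed.
#' @return named list of \linkS4class{DatasetBundle}.
#' @export
assembleSplits <- function(samples, fractions = c(train = 0.8, val = 0.1,
                                                  test = 0.1), seed = 1L) {
  if (!length(samples)) stop("invalid argument: empty sample list")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("invalid argument: fractions must sum to 1")
  n <- length(samples)
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  ord <- withSeed(seed, sample.int(n))
  out <- list()
  at <- 0L
  for (i in seq_along(fractions)) {
    nm <- names(fractions)[i] %||% as.character(i)
    idx <- if (sizes[i] > 0) ord[(at + 1L):(at + sizes[i])] else integer(0)
    at <- at + sizes[i]
    out[[nm]] <- new("DatasetBundle", splitName = nm,
                     samples = samples[idx],
                     provenance = list(seed = seed, fractions = as.list(fractions),
                                       n = n, indices = idx))
  }
  out
}

hasExt <- function(path, exts) any(vapply(exts, function(e)
  grepl(paste0("\\.", e, "$"), path, ignore.case = TRUE), logical(1)))

#' Read and write amplitude arrays
#'
#' Volumes and images round-trip through NIfTI (\code{.nii}/\code{.nii.gz},
#' double precision, bit-exact, carrying voxel sizes in the header) or TIFF
#' (\code{.tif}/\code{.tiff}, 32-bit samples quantized on [0, 1] to within
#' 2.4e-10 -- below single-precision resolution; 3D volumes become
#' multi-page stacks).  Malformed files raise a classed format error rather
#' than crashing.
#'
#' @param x numeric array (2D or 3D).
#' @param path file path; the extension selects the format.
#' @param pixelSize optional voxel sizes in micrometers (NIfTI only).
#' @return \code{writeVolume} returns \code{path} invisibly;
#'   \code{readVolume} returns the array, with a \code{pixelSize} attribute
#'   when the format carries one.
#' @export
writeVolume <- function(x, path, pixelSize = NULL) {
  if (hasExt(path, c("nii", "nii\\.gz"))) {
    if (!is.null(pixelSize)) attr(x, "pixdim") <- pixelSize
    RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"), path)
  } else if (hasExt(path, c("tif", "tiff"))) {
    if (length(dim(x)) == 3L) {
      pages <- lapply(seq_len(dim(x)[3]), function(z) x[, , z])
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    } else {
      tiff::writeTIFF(x, path, bits.per.sample = 32L)
    }
  } else stop("invalid argument: unsupported extension for ", path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("invalid argument: no such file: ", path)
  fmtError <- function(e) stop(structure(
    class = c("palocalFormatError", "error", "condition"),
    list(message = sprintf("format error reading '%s': %s", path,
                           conditionMessage(e)), call = NULL)))
  if (hasExt(path, c("nii", "nii\\.gz"))) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = fmtError)
    out <- as.array(img)
    attr(out, "pixelSize") <- RNifti::pixdim(img)
    out
  } else if (hasExt(path, c("tif", "tiff"))) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE), error = fmtError)
    if (length(pages) == 1L) pages[[1]]
    else array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  } else stop("invalid argument: unsupported extension for ", path)
}

#' Read and write localization event tables as CSV
#'
#' Columns: per-axis positions (grid units), amplitude, frame_index.
#'
#' @param events a \linkS4class{LocalizationEvents}.
#' @param path CSV path.
#' @param gridShape,superresFactor grid metadata for \code{readEventsCSV}.
#' @return the path (write) or a \linkS4class{LocalizationEvents} (read).
#' @export
writeEventsCSV <- function(events, path) {
  utils::write.csv(localEvents(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsCSV
#' @export
readEventsCSV <- function(path, gridShape, superresFactor = 1L) {
  e <- utils::read.csv(path)
  new("LocalizationEvents", events = e, gridShape = as.integer(gridShape),
      superresFactor = as.integer(superresFactor))
}

#' Write and read a dataset bundle
#'
#' A bundle is a directory holding a JSON manifest (split name, provenance,
#' sample formats) plus one NIfTI (3D) or TIFF (2D) file per sample array;
#' round-trips samples and provenance.
#'
#' @param bundle a \linkS4class{DatasetBundle}.
#' @param dir target directory (created if needed).
#' @return the directory (write) or a \linkS4class{DatasetBundle} (read).
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- if (length(bundle@samples))
    length(dim(bundle@samples[[1]]@y)) else NA_integer_
  ext <- if (identical(nd, 3L)) "nii" else "tif"
  manifest <- list(splitName = bundle@splitName,
                   provenance = bundle@provenance,
                   nSamples = length(bundle@samples), dim = nd, format = ext)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(bundle@samples)) {
    s <- bundle@samples[[i]]
    writeVolume(s@x, file.path(dir, sprintf("sample%04d_x.%s", i, ext)))
    writeVolume(s@y, file.path(dir, sprintf("sample%04d_y.%s", i, ext)))
  }
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop(structure(
    class = c("palocalFormatError", "error", "condition"),
    list(message = sprintf("format error: missing field 'manifest.json' in %s",
                           dir), call = NULL)))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  samples <- lapply(seq_len(manifest$nSamples), function(i) {
    x <- readVolume(file.path(dir, sprintf("sample%04d_x.%s", i, manifest$format)))
    y <- readVolume(file.path(dir, sprintf("sample%04d_y.%s", i, manifest$format)))
    attr(x, "pixelSize") <- NULL
    attr(y, "pixelSize") <- NULL
    # x is stored with its channel axis as the trailing array dimension
    if (length(dim(x)) == length(dim(y))) dim(x) <- c(dim(x), 1L)
    new("PairedSample", x = x, y = y)
  })
  new("DatasetBundle", splitName = manifest$splitName, samples = samples,
      provenance = manifest$provenance)
}
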