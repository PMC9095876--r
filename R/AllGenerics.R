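#' @include AllClasses.R
NULL

#' Accessors for palocal classes
#'
#' Small accessor family: \code{vesselSegments} returns the segment table of a
#' \linkS4class{VesselTree}; \code{frames} the frame list of a
#' \linkS4class{FrameSeries}; \code{imagingConfig} its configuration;
#' \code{localEvents} the event table of a \linkS4class{LocalizationEvents};
#' \code{asArray} the amplitude array of a \linkS4class{LocalizationImage};
#' \code{kUsed} and \code{nTotal} its contribution counts.
#'
#' @param object the object to access.
#' @return the accessed component.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("vesselSegments", function(object) standardGeneric("vesselSegments"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("imagingConfig", function(object) standardGeneric("imagingConfig"))
#' @rdname accessors
#' @export
setGeneric("localEvents", function(object) standardGeneric("localEvents"))
#' @rdname accessors
#' @export
setGeneric("asArray", function(object) standardGeneric("asArray"))
#' @rdname accessors
#' @export
setGeneric("kUsed", function(object) standardGeneric("kUsed"))
#' @rdname accessors
#' @export
setGeneric("nTotal", function(object) standardGeneric("nTotal"))

#' @rdname accessors
#' @export
setMethod("vesselSegments", "VesselTree", function(object) object@segments)
#' @rdname accessors
#' @export
setMethod("frames", "FrameSeries", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("imagingConfig", "FrameSeries", function(object) object@config)
#' @rdname accessors
#' @export
setMethod("localEvents", "LocalizationEvents", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("asArray", "LocalizationImage", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("kUsed", "LocalizationImage", function(object) object@kUsed)
#' @rdname accessors
#' @export
setMethod("nTotal", "LocalizationImage", function(object) object@nTotal)

#' Count of trainable scalars in a network or architecture spec
#'
#' On a built \linkS4class{PANetwork} this is the exact sum of parameter array
#' lengths; on a \linkS4class{GeneratorSpec} or
#' \linkS4class{DiscriminatorSpec} the same count is derived analytically from
#' the layer plan without allocating parameters.
#'
#' @param object a network or spec.
#' @return integer-valued numeric count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

setMethod("show", "VesselTree", function(object) {
  cat(sprintf("VesselTree: %d segment(s), dim %d, region %s um\n",
              nrow(object@segments), object@dim,
              paste(signif(object@region, 4), collapse = " x ")))
})

setMethod("show", "ImagingConfig", function(object) {
  cat(sprintf("ImagingConfig: grid %s, pixel %s um, PSF FWHM %s um, noise sd %g\n",
              paste(object@gridShape, collapse = "x"),
              paste(object@pixelSize, collapse = "/"),
              paste(object@psfFWHM, collapse = "/"), object@noiseSD))
})

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("FrameSeries: %d frame(s) of %s, %.3g s/frame (total %.3g s)\n",
              length(object@frames),
              paste(object@config@gridShape, collapse = "x"),
              object@perFrameTime, totalAcquisitionTime(object)))
})

setMethod("show", "LocalizationEvents", function(object) {
  cat(sprintf("LocalizationEvents: %d event(s) over %d frame(s), grid %s\n",
              nrow(object@events),
              length(unique(object@events$frame_index)),
              paste(object@gridShape, collapse = "x")))
})

setMethod("show", "LocalizationImage", function(object) {
  cat(sprintf("LocalizationImage: %s, k=%d of N=%d, superres factor %d\n",
              paste(dim(object@data), collapse = "x"),
              object@kUsed, object@nTotal, object@superresFactor))
})

setMethod("show", "PANetwork", function(object) {
  cat(sprintf("PANetwork (%s, %dD): %d conv layer(s), %s trainable parameters\n",
              object@role, object@spec@dim,
              sum(vapply(object@plan, function(l)
                l$type %in% c("conv", "upconv"), logical(1))),
              format(countParameters(object), big.mark = ",")))
})

setMethod("show", "DatasetBundle", function(object) {
  cat(sprintf("DatasetBundle '%s': %d paired sample(s)\n",
              object@splitName, length(object@samples)))
})
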