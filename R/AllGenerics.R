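#' Accessors for volume-like objects
#'
#' \code{voxelData} returns the raw 3D array, \code{voxelSpacing} the
#' (slice, row, col) spacing in mm, \code{modality} the modality tag and
#' \code{intensityRange} the physical range recorded for normalization.
#'
#' @param x a \linkS4class{ScanVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{BodyMask}.
#' @param value replacement value.
#' @return The requested component (or the modified object for setters).
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname volume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname volume-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname volume-accessors
#' @export
setGeneric("intensityRange", function(x) standardGeneric("intensityRange"))

#' @rdname volume-accessors
#' @export
setGeneric("intensityRange<-",
           function(x, value) standardGeneric("intensityRange<-"))

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "ScanVolume", function(x) x@data)

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@labels)

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "BodyMask", function(x) x@mask)

#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "ScanVolume", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "BodyMask", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("modality", "ScanVolume", function(x) x@modality)

#' @rdname volume-accessors
#' @export
setMethod("intensityRange", "ScanVolume", function(x) x@intensityRange)

#' @rdname volume-accessors
#' @export
setReplaceMethod("intensityRange", "ScanVolume", function(x, value) {
    x@intensityRange <- as.numeric(value)
    validObject(x)
    x
})

#' Number of patches in a PatchGrid
#' @param x a \linkS4class{PatchGrid}.
#' @return Integer patch count.
#' @export
setMethod("length", "PatchGrid", function(x) length(x@patches))

#' @rdname volume-accessors
#' @export
setGeneric("patchOrigins", function(x) standardGeneric("patchOrigins"))

#' @rdname volume-accessors
#' @export
setMethod("patchOrigins", "PatchGrid", function(x) x@origins)

#' @rdname volume-accessors
#' @export
setGeneric("patchData", function(x) standardGeneric("patchData"))

#' @rdname volume-accessors
#' @export
setMethod("patchData", "PatchGrid", function(x) x@patches)
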