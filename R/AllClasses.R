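#' @import methods
NULL

## Axis convention used throughout the package: (slice, row, col), 0-based
## patch origins. An axial slice is vol@data[k, , ].

#' ScanVolume: a 3D scalar medical volume
#'
#' The universal image carrier: a 3D numeric array with axes ordered
#' (slice, row, col), physical voxel spacing in mm, a modality tag and the
#' physical intensity range used for normalization. For CT the working range
#' after preprocessing is fixed at -1000..+1047 HU; for MRI it is the
#' per-volume (min, max) in arbitrary units.
#'
#' @slot data 3D numeric array, axes (slice, row, col).
#' @slot spacing numeric length-3, voxel spacing in mm (slice, row, col);
#'   strictly positive.
#' @slot modality one of \code{"CT"}, \code{"MRI"}, \code{"DOSE"},
#'   \code{"GENERIC"}.
#' @slot intensityRange numeric length-2 \code{(lo, hi)} with
#'   \code{lo < hi}, or \code{c(NA, NA)} when not yet set.
#' @exportClass ScanVolume
setClass("ScanVolume",
    representation(
        data = "array",
        spacing = "numeric",
        modality = "character",
        intensityRange = "numeric"
    ),
    prototype(
        data = array(0, dim = c(1, 1, 1)),
        spacing = c(1, 1, 1),
        modality = "GENERIC",
        intensityRange = c(NA_real_, NA_real_)
    )
)

setValidity("ScanVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3D array (slice, row, col)")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
    if (!object@modality %in% c("CT", "MRI", "DOSE", "GENERIC"))
        msg <- c(msg, "modality must be CT, MRI, DOSE or GENERIC")
    ir <- object@intensityRange
    if (length(ir) != 2L)
        msg <- c(msg, "intensityRange must have length 2")
    else if (all(is.finite(ir)) && ir[1] >= ir[2])
        msg <- c(msg, "intensityRange must satisfy lo < hi")
    if (object@modality == "DOSE" && any(object@data < 0))
        msg <- c(msg, "DOSE volumes must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a ScanVolume
#'
#' @param data 3D numeric array ordered (slice, row, col).
#' @param spacing voxel spacing in mm, length 3 (slice, row, col).
#' @param modality \code{"CT"}, \code{"MRI"}, \code{"DOSE"} or
#'   \code{"GENERIC"}.
#' @param intensityRange physical range \code{c(lo, hi)} used by
#'   normalization, or \code{NULL} if unset.
#' @return A \linkS4class{ScanVolume}.
#' @examples
#' v <- ScanVolume(array(0, c(2, 4, 4)), spacing = c(2, 1.0625, 1.0625),
#'                 modality = "CT")
#' voxelSpacing(v)
#' @export
ScanVolume <- function(data, spacing = c(1, 1, 1), modality = "GENERIC",
                       intensityRange = NULL) {
    if (is.null(intensityRange)) intensityRange <- c(NA_real_, NA_real_)
    new("ScanVolume", data = data, spacing = as.numeric(spacing),
        modality = modality, intensityRange = as.numeric(intensityRange))
}

#' LabelVolume: integer organ label map
#'
#' Non-negative integer grid with the same geometry contract as
#' \linkS4class{ScanVolume}; label 0 is background (air).
#'
#' @slot labels 3D integer array (slice, row, col), values >= 0.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @exportClass LabelVolume
setClass("LabelVolume",
    representation(labels = "array", spacing = "numeric"),
    prototype(labels = array(0L, dim = c(1, 1, 1)), spacing = c(1, 1, 1))
)

setValidity("LabelVolume", function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
        msg <- c(msg, "labels must be a 3D array")
    if (!is.integer(object@labels) && !all(object@labels == round(object@labels)))
        msg <- c(msg, "labels must be integers")
    if (any(object@labels < 0))
        msg <- c(msg, "labels must be non-negative")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
    if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#' @param labels 3D non-negative integer array (slice, row, col).
#' @param spacing voxel spacing in mm, length 3.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, spacing = c(1, 1, 1)) {
    storage.mode(labels) <- "integer"
    new("LabelVolume", labels = labels, spacing = as.numeric(spacing))
}

#' TissueTable: per-label tissue properties
#'
#' Lookup table mapping integer organ labels to a tissue name, the linear
#' attenuation coefficient mu at 120 keV (1/cm) and a representative MRI
#' intensity (a.u.). Label 0 is air with mu = 0. The water attenuation
#' coefficient used for HU conversion is carried alongside.
#'
#' @slot table data.frame with columns \code{label}, \code{name},
#'   \code{mu_120kev}, \code{mri_intensity}.
#' @slot muWater water attenuation coefficient at 120 keV (1/cm).
#' @exportClass TissueTable
setClass("TissueTable",
    representation(table = "data.frame", muWater = "numeric"),
    prototype(table = data.frame(label = integer(), name = character(),
                                 mu_120kev = numeric(),
                                 mri_intensity = numeric()),
              muWater = 0.1615)
)

setValidity("TissueTable", function(object) {
    tb <- object@table
    msg <- character()
    need <- c("label", "name", "mu_120kev", "mri_intensity")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(tb$label))
        msg <- c(msg, "labels must be unique")
    if (any(tb$mu_120kev < 0))
        msg <- c(msg, "mu_120kev must be >= 0")
    if (0L %in% tb$label && any(tb$mu_120kev[tb$label == 0L] != 0))
        msg <- c(msg, "label 0 must map to air (mu = 0)")
    if (length(object@muWater) != 1L || object@muWater <= 0)
        msg <- c(msg, "muWater must be a single positive value")
    if (length(msg)) msg else TRUE
})

#' Construct a TissueTable
#' @param table data.frame with columns \code{label}, \code{name},
#'   \code{mu_120kev}, \code{mri_intensity}.
#' @param muWater water linear attenuation coefficient at 120 keV in 1/cm
#'   (default 0.1615).
#' @return A \linkS4class{TissueTable}.
#' @export
TissueTable <- function(table, muWater = 0.1615) {
    table$label <- as.integer(table$label)
    new("TissueTable", table = table, muWater = muWater)
}

#' BodyMask: binary body-region mask
#'
#' Per-slice binary foreground produced by the CT body-masking chain
#' (threshold, hole filling, edge refinement, largest component).
#'
#' @slot mask 3D logical array with the geometry of its source volume.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @exportClass BodyMask
setClass("BodyMask",
    representation(mask = "array", spacing = "numeric"),
    prototype(mask = array(FALSE, dim = c(1, 1, 1)), spacing = c(1, 1, 1))
)

setValidity("BodyMask", function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
    TRUE
})

#' Construct a BodyMask
#' @param mask 3D logical array (slice, row, col).
#' @param spacing voxel spacing in mm, length 3.
#' @return A \linkS4class{BodyMask}.
#' @export
BodyMask <- function(mask, spacing = c(1, 1, 1)) {
    storage.mode(mask) <- "logical"
    new("BodyMask", mask = mask, spacing = as.numeric(spacing))
}

#' PatchGrid: a set of 2D patches with exact provenance
#'
#' Each patch records the axial slice index and its 0-based (row, col)
#' origin within that slice, so mean fusion can reconstruct the source
#' geometry exactly.
#'
#' @slot patches list of numeric matrices (native patch size).
#' @slot origins integer matrix with columns \code{slice}, \code{row0},
#'   \code{col0} (0-based).
#' @slot patchSize native square patch side in pixels.
#' @slot sourceDim integer length-3 dims of the source volume
#'   (slice, row, col).
#' @exportClass PatchGrid
setClass("PatchGrid",
    representation(
        patches = "list",
        origins = "matrix",
        patchSize = "integer",
        sourceDim = "integer"
    )
)

setValidity("PatchGrid", function(object) {
    msg <- character()
    n <- length(object@patches)
    if (nrow(object@origins) != n)
        msg <- c(msg, "one origin row per patch required")
    if (n > 0) {
        p <- object@patchSize
        d <- object@sourceDim
        if (any(object@origins[, 2] < 0) || any(object@origins[, 3] < 0) ||
            any(object@origins[, 2] + p > d[2]) ||
            any(object@origins[, 3] + p > d[3]))
            msg <- c(msg, "every patch must lie fully inside its slice")
    }
    if (length(msg)) msg else TRUE
})

#' DVHCurve: cumulative dose-volume histogram
#'
#' Empirical cumulative curve V(d): the fraction of the structure receiving
#' at least dose d, with each masked voxel carrying equal weight.
#'
#' @slot dose dose axis in Gy (sorted ascending, unique voxel doses).
#' @slot volumeFraction V(d) at each dose axis point, in [0, 1],
#'   non-increasing.
#' @slot voxelDoses raw masked voxel doses (ascending) for exact quantiles.
#' @slot structure structure name.
#' @exportClass DVHCurve
setClass("DVHCurve",
    representation(
        dose = "numeric",
        volumeFraction = "numeric",
        voxelDoses = "numeric",
        structure = "character"
    )
)

setValidity("DVHCurve", function(object) {
    msg <- character()
    if (is.unsorted(object@dose))
        msg <- c(msg, "dose axis must be ascending")
    v <- object@volumeFraction
    if (length(v) != length(object@dose))
        msg <- c(msg, "dose and volumeFraction lengths differ")
    if (length(v) && (any(v < 0) || any(v > 1) || is.unsorted(rev(v))))
        msg <- c(msg, "volumeFraction must be non-increasing within [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ScanVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("ScanVolume [%s]: %d x %d x %d (slice,row,col), spacing %s mm\n",
                object@modality, d[1], d[2], d[3],
                paste(format(object@spacing, digits = 5), collapse = " x ")))
    ir <- object@intensityRange
    if (all(is.finite(ir)))
        cat(sprintf("  intensity range: [%g, %g]\n", ir[1], ir[2]))
    rng <- range(object@data)
    cat(sprintf("  voxel values in [%g, %g]\n", rng[1], rng[2]))
})

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@labels)
    labs <- sort(unique(as.vector(object@labels)))
    cat(sprintf("LabelVolume: %d x %d x %d, %d labels (%s)\n",
                d[1], d[2], d[3], length(labs),
                paste(utils::head(labs, 10), collapse = ", ")))
})

setMethod("show", "TissueTable", function(object) {
    cat(sprintf("TissueTable: %d tissues, muWater = %g 1/cm\n",
                nrow(object@table), object@muWater))
    print(utils::head(object@table, 10))
})

setMethod("show", "PatchGrid", function(object) {
    cat(sprintf("PatchGrid: %d patches of %d x %d from source %s\n",
                length(object@patches), object@patchSize, object@patchSize,
                paste(object@sourceDim, collapse = " x ")))
})

setMethod("show", "BodyMask", function(object) {
    cat(sprintf("BodyMask: %s, %d foreground voxels\n",
                paste(dim(object@mask), collapse = " x "), sum(object@mask)))
})

setMethod("show", "DVHCurve", function(object) {
    cat(sprintf("DVHCurve '%s': %d voxels, dose range [%g, %g] Gy\n",
                object@structure, length(object@voxelDoses),
                min(object@voxelDoses), max(object@voxelDoses)))
})
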