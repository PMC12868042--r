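#' Patient-specific piecewise-constant phantom from an organ label map
#'
#' Assigns every labelled organ its phantom CT number (from the tissue
#' table's attenuation coefficients) in the patient's own geometry; label
#' 0 becomes air at -1000 HU. This is the construction used for hold-out
#' and external validation: the resulting phantom is fed through the
#' trained phantom-to-patient generator and compared against the real
#' patient CT. Identical to [renderCT()] applied to an externally
#' supplied segmentation.
#'
#' @param labels \linkS4class{LabelVolume} segmentation of the patient.
#' @param tissues \linkS4class{TissueTable} covering all nonzero labels.
#' @return Piecewise-constant CT \linkS4class{ScanVolume}.
#' @export
labelsToPhantom <- function(labels, tissues) {
    present <- setdiff(sort(unique(as.vector(voxelData(labels)))), 0L)
    missing <- setdiff(present, tissues@table$label)
    if (length(missing))
        stop("labels missing from the tissue table: ",
             paste(missing, collapse = ", "))
    renderCT(labels, tissues)
}

#' Paired evaluation of a realistic phantom against the patient CT
#'
#' Delegates to [pairedReport()] over all co-registered slices, the
#' slice-by-slice comparison used for hold-out and external validation.
#'
#' @param phantomRealistic generated realistic CT \linkS4class{ScanVolume}.
#' @param patientCT original patient CT \linkS4class{ScanVolume} with the
#'   same geometry.
#' @param ... further arguments passed to [pairedReport()].
#' @return A \linkS4class{PairedReport}.
#' @export
validateAgainstPatient <- function(phantomRealistic, patientCT, ...) {
    if (!all(dim(voxelData(phantomRealistic)) == dim(voxelData(patientCT))))
        stop("phantom and patient volumes are not co-registered")
    pairedReport(phantomRealistic, patientCT, ...)
}
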