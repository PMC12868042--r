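## Dose-volume-histogram summaries for comparing a reference plan against
## a recalculation on a generated CT: cumulative DVH curves, the Dp%
## family (D95% for targets, D2% for organs at risk), and plan-level
## difference tables.

#' Cumulative dose-volume histogram of a structure
#'
#' Empirical cumulative curve V(d) = fraction of masked voxels receiving
#' at least dose d (each voxel equal weight; no smoothing, no
#' partial-volume weighting).
#'
#' @param dose a DOSE \linkS4class{ScanVolume} (Gy) or 3D array.
#' @param mask logical array, \linkS4class{BodyMask}, or
#'   \linkS4class{LabelVolume} + \code{label} selecting the structure.
#' @param label structure label for \linkS4class{LabelVolume} masks.
#' @param structure structure name stored on the curve.
#' @return A \linkS4class{DVHCurve}.
#' @export
dvh <- function(dose, mask, label = NULL, structure = "structure") {
    x <- if (is(dose, "ScanVolume")) voxelData(dose) else dose
    m <- if (is(mask, "LabelVolume")) {
        if (is.null(label)) stop("a label is required with a LabelVolume mask")
        voxelData(mask) == label
    } else if (is(mask, "BodyMask")) voxelData(mask) else mask
    if (!all(dim(x) == dim(m))) stop("dose and mask geometries differ")
    if (!any(m)) stop("empty structure mask")
    v <- sort(x[m])
    n <- length(v)
    ud <- unique(v)
    vf <- vapply(ud, function(d0) mean(v >= d0), numeric(1))
    new("DVHCurve", dose = ud, volumeFraction = vf, voxelDoses = v,
        structure = structure)
}

#' Dp%: dose received by at least p% of a structure
#'
#' The largest dose d with V(d) >= p/100: the empirical (100 - p)th
#' percentile of the masked voxel doses with the higher-value tie
#' convention. D95% is the minimum dose that 95% of a target receives;
#' D2% the maximum dose received by the most exposed 2% of an organ at
#' risk.
#'
#' @param curve a \linkS4class{DVHCurve}.
#' @param p percent in (0, 100).
#' @return Dose in Gy.
#' @export
dPercent <- function(curve, p) {
    if (p <= 0 || p >= 100) stop("p must lie strictly between 0 and 100")
    v <- curve@voxelDoses              # ascending
    n <- length(v)
    k <- ceiling(p / 100 * n)          # k-th largest has V(d) >= p/100
    v[n - k + 1L]
}

#' Compare a reference and a recalculated dose distribution
#'
#' For every target structure the D95% difference is reported with the
#' relative error against the prescribed dose; for every organ at risk
#' the D2% difference is reported with the relative error against the
#' reference plan's own metric. Differences are recalculated minus
#' reference.
#'
#' @param refDose,recalcDose DOSE \linkS4class{ScanVolume}s (or arrays)
#'   on the same grid.
#' @param masks named list of logical structure masks.
#' @param targets names of target structures (use D95%).
#' @param oars names of organ-at-risk structures (use D2%).
#' @param prescribed prescribed dose in Gy (denominator for targets).
#' @return data.frame with structure, metric, reference and recalculated
#'   values, \code{delta} (Gy) and \code{relErrPct}.
#' @export
comparePlans <- function(refDose, recalcDose, masks,
                         targets = character(), oars = character(),
                         prescribed) {
    one <- function(nm, p, denom) {
        cr <- dvh(refDose, masks[[nm]], structure = nm)
        cc <- dvh(recalcDose, masks[[nm]], structure = nm)
        vr <- dPercent(cr, p); vc <- dPercent(cc, p)
        delta <- vc - vr
        den <- if (identical(denom, "prescribed")) prescribed else vr
        data.frame(structure = nm,
                   metric = sprintf("D%g%%", p),
                   reference = vr, recalculated = vc, delta = delta,
                   relErrPct = if (den == 0) NA_real_
                               else 100 * delta / den)
    }
    rows <- c(lapply(targets, one, p = 95, denom = "prescribed"),
              lapply(oars, one, p = 2, denom = "plan"))
    do.call(rbind, rows)
}
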