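## Fixed CT working range in HU used across the pipeline.
.CT_LO <- -1000
.CT_HI <- 1047

#' Clip a CT volume to the working HU range
#'
#' Clamps all voxels to [-1000, +1047] HU and records that range as the
#' volume's intensity range for later normalization. Idempotent.
#'
#' @param vol a CT \linkS4class{ScanVolume}.
#' @return The clipped \linkS4class{ScanVolume}.
#' @export
clipCT <- function(vol) {
    if (modality(vol) != "CT")
        stop("clipCT expects a CT volume, got modality ", modality(vol))
    d <- voxelData(vol)
    d[d < .CT_LO] <- .CT_LO
    d[d > .CT_HI] <- .CT_HI
    ScanVolume(d, spacing = voxelSpacing(vol), modality = "CT",
               intensityRange = c(.CT_LO, .CT_HI))
}

.sobelX <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
.sobelY <- t(.sobelX)

.conv3x3 <- function(m, k) {
    ## 'same' convolution with zero border, small kernel, pure R
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    for (di in -1:1) for (dj in -1:1) {
        wgt <- k[di + 2, dj + 2]
        if (wgt == 0) next
        src <- m[pmin(pmax(seq_len(h) + di, 1), h),
                 pmin(pmax(seq_len(w) + dj, 1), w)]
        out <- out + wgt * src
    }
    out
}

.largestComponent <- function(bin) {
    if (!any(bin)) return(bin)
    lab <- EBImage::bwlabel(bin * 1)
    tab <- tabulate(lab[lab > 0])
    array(lab == which.max(tab), dim(bin))
}

.bodyMaskSlice <- function(slice, thresholdHU = -110) {
    bin <- slice >= thresholdHU
    if (!any(bin)) return(bin)
    filled <- EBImage::fillHull(bin * 1) > 0
    ## Edge refinement: Sobel gradient magnitude of the binary mask marks the
    ## boundary band; dilating it by one pixel closes single-pixel leaks
    ## before hole filling is repeated.
    gx <- .conv3x3(filled * 1, .sobelX)
    gy <- .conv3x3(filled * 1, .sobelY)
    edge <- (sqrt(gx^2 + gy^2) > 0) * 1
    edge <- EBImage::dilate(edge, EBImage::makeBrush(3, shape = "box"))
    refined <- EBImage::fillHull(pmax(filled * 1, edge)) > 0
    ## The dilated edge band grew the outline by two pixels; erode it back
    ## and take the union with the filled mask so the boundary tracks the
    ## thresholded body outline while leak-closed interior fills survive.
    refined <- EBImage::erode(refined * 1,
                              EBImage::makeBrush(5, shape = "box")) > 0
    refined <- refined | filled
    .largestComponent(refined)
}

#' Body mask from a clipped CT volume
#'
#' Per-slice chain: threshold at -110 HU, binary hole filling, Sobel-based
#' edge refinement (close gaps along the boundary band), then retention of
#' the largest connected component. Slices with no foreground yield an
#' empty mask slice.
#'
#' @param vol a clipped CT \linkS4class{ScanVolume}.
#' @param thresholdHU foreground threshold in HU (default -110).
#' @return A \linkS4class{BodyMask}.
#' @export
bodyMask <- function(vol, thresholdHU = -110) {
    if (modality(vol) != "CT")
        stop("bodyMask expects a CT volume")
    arr <- voxelData(vol)
    d <- dim(arr)
    out <- array(FALSE, d)
    for (k in seq_len(d[1])) {
        sl <- array(arr[k, , ], dim = d[2:3])
        out[k, , ] <- .bodyMaskSlice(sl, thresholdHU)
    }
    BodyMask(out, spacing = voxelSpacing(vol))
}

#' Suppress the background outside a body mask
#'
#' Voxels outside the mask are set to -1000 HU for CT and 0 for other
#' modalities; voxels inside are untouched.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param mask a \linkS4class{BodyMask} with matching geometry.
#' @return The background-suppressed \linkS4class{ScanVolume}.
#' @export
applyBackground <- function(vol, mask) {
    arr <- voxelData(vol)
    m <- voxelData(mask)
    if (!identical(dim(arr), dim(m)))
        stop("volume and mask shapes differ")
    bg <- if (modality(vol) == "CT") .CT_LO else 0
    arr[!m] <- bg
    ScanVolume(arr, spacing = voxelSpacing(vol), modality = modality(vol),
               intensityRange = intensityRange(vol))
}

#' Rescale a volume linearly to [-1, +1]
#'
#' Maps \code{lo -> -1} and \code{hi -> +1} where \code{(lo, hi)} is the
#' volume's physical intensity range: the fixed -1000..+1047 HU window for
#' CT, the per-volume (min, max) for MRI (computed and recorded here when
#' unset). The range is stored on the result so [denormalizeVolume()] is an
#' exact inverse.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @return Normalized \linkS4class{ScanVolume} with values in [-1, 1].
#' @export
normalizeVolume <- function(vol) {
    ir <- intensityRange(vol)
    if (any(!is.finite(ir))) {
        ir <- if (modality(vol) == "CT") c(.CT_LO, .CT_HI)
              else range(voxelData(vol))
    }
    if (ir[2] <= ir[1])
        stop("degenerate intensity range [", ir[1], ", ", ir[2], "]")
    d <- 2 * (voxelData(vol) - ir[1]) / (ir[2] - ir[1]) - 1
    ScanVolume(d, spacing = voxelSpacing(vol), modality = modality(vol),
               intensityRange = ir)
}

#' Invert [-1, 1] normalization onto a physical range
#'
#' Exact linear inverse of [normalizeVolume()]. Values are clamped to
#' [-1, 1] first to absorb tiny generator overshoots beyond the tanh range.
#'
#' @param vol a normalized \linkS4class{ScanVolume}.
#' @param range physical range \code{c(lo, hi)}; defaults to the range
#'   recorded on \code{vol}.
#' @return Denormalized \linkS4class{ScanVolume}.
#' @export
denormalizeVolume <- function(vol, range = intensityRange(vol)) {
    if (length(range) != 2L || any(!is.finite(range)))
        stop("a physical intensity range is required for denormalization")
    d <- voxelData(vol)
    d[d < -1] <- -1
    d[d > 1] <- 1
    d <- (d + 1) / 2 * (range[2] - range[1]) + range[1]
    ScanVolume(d, spacing = voxelSpacing(vol), modality = modality(vol),
               intensityRange = range)
}
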