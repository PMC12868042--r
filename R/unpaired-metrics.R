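## Realism statistics without correspondence: noise magnitude inside a
## homogeneous organ (the liver in practice), the radially averaged noise
## power spectrum of an ROI, and cohort-level intensity-histogram
## correlation.

#' Noise magnitude inside an organ mask
#'
#' Population standard deviation of the voxel intensities within the mask
#' (the liver is the organ of choice: large and mostly homogeneous).
#' Cohort-level values are the mean over volumes.
#'
#' @param vol a \linkS4class{ScanVolume} (or 3D array).
#' @param mask logical array, \linkS4class{BodyMask}, or
#'   \linkS4class{LabelVolume} with \code{label} selecting the organ.
#' @param label organ label when \code{mask} is a
#'   \linkS4class{LabelVolume}.
#' @return Noise magnitude (HU or a.u.).
#' @export
noiseMagnitude <- function(vol, mask, label = NULL) {
    x <- if (is(vol, "ScanVolume")) voxelData(vol) else vol
    m <- if (is(mask, "LabelVolume")) {
        if (is.null(label)) stop("a label is required with a LabelVolume mask")
        voxelData(mask) == label
    } else if (is(mask, "BodyMask")) voxelData(mask) else mask
    if (!any(m)) stop("empty organ mask")
    v <- x[m]
    sqrt(mean((v - mean(v))^2))
}

#' Radially averaged noise power spectrum of a 3D ROI
#'
#' Per axial ROI slice: subtract the slice mean, 2D FFT, squared modulus
#' scaled by \code{dx*dy/(Nx*Ny)}; slices are averaged and the 2D spectrum
#' binned into equal-width radial spatial-frequency annuli. Absolute scale
#' follows this convention; downstream comparisons only use the Pearson
#' correlation of curves, which is scale-free.
#'
#' @param roi 3D numeric array (slice, row, col), at least 16 x 16
#'   in-plane (the working ROI is 64 x 64 x 20 voxels).
#' @param spacing voxel spacing in mm (slice, row, col) or in-plane pair.
#' @param nbins number of radial bins (default: half the smaller in-plane
#'   size).
#' @return data.frame with \code{freq} (1/mm, bin centers) and
#'   \code{power}.
#' @export
radialNPS <- function(roi, spacing = c(1, 1, 1), nbins = NULL) {
    d <- dim(roi)
    if (length(d) != 3L) stop("roi must be a 3D array")
    if (d[2] < 16L || d[3] < 16L)
        stop("ROI must be at least 16 x 16 in-plane")
    sp <- if (length(spacing) == 3L) spacing[2:3] else spacing
    acc <- matrix(0, d[2], d[3])
    for (k in seq_len(d[1])) {
        sl <- array(roi[k, , ], d[2:3])
        sl <- sl - mean(sl)
        acc <- acc + Mod(stats::fft(sl))^2 * prod(sp) / (d[2] * d[3])
    }
    nps2d <- acc / d[1]
    fr <- matrix(.fftFreq(d[2]) / sp[1], d[2], d[3])
    fc <- matrix(.fftFreq(d[3]) / sp[2], d[2], d[3], byrow = TRUE)
    rad <- sqrt(fr^2 + fc^2)
    fmax <- min(0.5 / sp)
    if (is.null(nbins)) nbins <- min(d[2], d[3]) %/% 2L
    edges <- seq(0, fmax, length.out = nbins + 1L)
    bin <- findInterval(rad, edges, rightmost.closed = TRUE)
    keep <- bin >= 1L & bin <= nbins & rad > 0
    power <- vapply(seq_len(nbins), function(i) {
        v <- nps2d[keep & bin == i]
        if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out <- data.frame(freq = (edges[-1] + edges[-(nbins + 1L)]) / 2,
                      power = power)
    out[!is.na(out$power), ]
}

#' Pearson correlation between two radial NPS curves
#'
#' @param c1,c2 curves from [radialNPS()] with identical binning.
#' @return Pearson correlation coefficient.
#' @export
npsCorrelation <- function(c1, c2) {
    if (nrow(c1) != nrow(c2) || max(abs(c1$freq - c2$freq)) > 1e-9)
        stop("NPS curves must share the same frequency binning")
    stats::cor(c1$power, c2$power)
}

#' Cohort-level intensity-histogram correlation (HistCC)
#'
#' Per-volume density histograms on shared bin edges are averaged within
#' each cohort and the Pearson correlation between the two mean
#' histograms is returned. CT cohorts default to fixed 10-HU bins over
#' the clip window; otherwise 128 bins span the pooled range. Background
#' can be excluded via per-volume masks (body-only histograms).
#'
#' @param cohortA,cohortB lists of \linkS4class{ScanVolume}s (or arrays).
#' @param breaks bin edges (default: modality-dependent as above).
#' @param masksA,masksB optional lists of logical arrays /
#'   \linkS4class{BodyMask}s restricting the histograms.
#' @return Pearson correlation of the two cohort-mean histograms.
#' @export
histCorrelation <- function(cohortA, cohortB, breaks = NULL,
                            masksA = NULL, masksB = NULL) {
    if (!length(cohortA) || !length(cohortB))
        stop("both cohorts must be non-empty")
    getArr <- function(v) if (is(v, "ScanVolume")) voxelData(v) else v
    vals <- function(v, m) {
        a <- getArr(v)
        if (is.null(m)) as.vector(a)
        else a[if (is(m, "BodyMask")) voxelData(m) else m]
    }
    isCT <- all(vapply(c(cohortA, cohortB), function(v)
        is(v, "ScanVolume") && modality(v) == "CT", logical(1)))
    if (is.null(breaks)) {
        breaks <- if (isCT) seq(-1000, 1050, by = 10) else {
            rng <- range(vapply(c(cohortA, cohortB), function(v)
                range(getArr(v)), numeric(2)))
            seq(rng[1], rng[2], length.out = 129)
        }
    }
    densOf <- function(v, m) {
        x <- vals(v, m)
        x <- x[x >= breaks[1] & x <= breaks[length(breaks)]]
        h <- graphics::hist(x, breaks = breaks, plot = FALSE)
        h$counts / sum(h$counts)
    }
    hA <- mapply(densOf, cohortA,
                 if (is.null(masksA)) vector("list", length(cohortA))
                 else masksA, SIMPLIFY = TRUE)
    hB <- mapply(densOf, cohortB,
                 if (is.null(masksB)) vector("list", length(cohortB))
                 else masksB, SIMPLIFY = TRUE)
    stats::cor(rowMeans(as.matrix(hA)), rowMeans(as.matrix(hB)))
}

#' Largest axis-aligned ROI box inside a mask
#'
#' Helper for NPS ROI placement: finds an origin where a box of the
#' requested size lies entirely inside the organ mask (ROI placement was
#' manual in the original protocol; this automates the common case).
#'
#' @param mask logical 3D array or \linkS4class{LabelVolume} +
#'   \code{label}.
#' @param size box size (slice, row, col); default c(20, 64, 64).
#' @param label organ label when \code{mask} is a
#'   \linkS4class{LabelVolume}.
#' @return List with \code{origin} (1-based) and \code{size}; error if no
#'   such box exists.
#' @export
largestBoxROI <- function(mask, size = c(20L, 64L, 64L), label = NULL) {
    m <- if (is(mask, "LabelVolume")) {
        if (is.null(label)) stop("a label is required with a LabelVolume mask")
        voxelData(mask) == label
    } else mask
    d <- dim(m)
    size <- pmin(as.integer(size), d)
    cs <- apply(array(as.numeric(m), d), c(2, 3), cumsum)
    cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3))
    cs <- aperm(apply(cs, c(1, 2), cumsum), c(2, 3, 1))
    boxSum <- function(o) {
        hi <- o + size - 1L
        s <- function(i, j, k) if (i < 1 || j < 1 || k < 1) 0 else cs[i, j, k]
        s(hi[1], hi[2], hi[3]) - s(o[1] - 1, hi[2], hi[3]) -
            s(hi[1], o[2] - 1, hi[3]) - s(hi[1], hi[2], o[3] - 1) +
            s(o[1] - 1, o[2] - 1, hi[3]) + s(o[1] - 1, hi[2], o[3] - 1) +
            s(hi[1], o[2] - 1, o[3] - 1) - s(o[1] - 1, o[2] - 1, o[3] - 1)
    }
    target <- prod(size)
    for (i in seq_len(d[1] - size[1] + 1L))
        for (j in seq_len(d[2] - size[2] + 1L))
            for (k in seq_len(d[3] - size[3] + 1L))
                if (boxSum(c(i, j, k)) == target)
                    return(list(origin = c(i, j, k), size = size))
    stop("no fully enclosed box of the requested size exists in the mask")
}

#' Extract a sub-volume ROI
#'
#' @param vol a \linkS4class{ScanVolume} or 3D array.
#' @param origin 1-based origin (slice, row, col).
#' @param size box size (slice, row, col).
#' @return 3D numeric array.
#' @export
extractROI <- function(vol, origin, size) {
    a <- if (is(vol, "ScanVolume")) voxelData(vol) else vol
    a[origin[1] + seq_len(size[1]) - 1L,
      origin[2] + seq_len(size[2]) - 1L,
      origin[3] + seq_len(size[3]) - 1L, drop = FALSE]
}
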