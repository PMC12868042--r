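## Slice-wise paired similarity between a generated volume and its
## reference: intensity (MAE), structure (SSIM), features (FSIM), edges
## (Canny-based preservation/generation ratios), optional perceptual
## distance through a pluggable backend, and the synthetic-CT validation
## metrics (PSNR, NCC, RMSE, per-channel MAE).

#' Mean absolute error
#' @param a,b numeric arrays of identical shape.
#' @param mask optional logical mask restricting the average.
#' @return Mean of \code{|a - b|} over the mask (all voxels by default).
#' @export
mae <- function(a, b, mask = NULL) {
    if (!all(dim(a) == dim(b))) stop("shape mismatch")
    d <- abs(a - b)
    if (is.null(mask)) mean(d) else {
        if (!any(mask)) stop("empty mask")
        mean(d[mask])
    }
}

#' Root mean squared error
#' @inheritParams mae
#' @return \code{sqrt(mean((a - b)^2))}.
#' @export
rmse <- function(a, b, mask = NULL) {
    if (!all(dim(a) == dim(b))) stop("shape mismatch")
    d <- (a - b)^2
    sqrt(if (is.null(mask)) mean(d) else mean(d[mask]))
}

#' Peak signal-to-noise ratio in dB
#' @inheritParams mae
#' @param dataRange dynamic range of the signal (CT default 2047, the
#'   clip-window span).
#' @return \code{20*log10(dataRange) - 10*log10(MSE)}; \code{Inf} for
#'   identical inputs.
#' @export
psnr <- function(a, b, dataRange = 2047) {
    mse <- mean((a - b)^2)
    if (mse == 0) return(Inf)
    20 * log10(dataRange) - 10 * log10(mse)
}

#' Normalized cross correlation (Pearson)
#' @inheritParams mae
#' @return Pearson correlation of the flattened voxel vectors; affine
#'   transformations of either input leave it unchanged.
#' @export
ncc <- function(a, b) {
    av <- as.vector(a); bv <- as.vector(b)
    if (stats::sd(av) == 0 || stats::sd(bv) == 0)
        stop("NCC undefined for zero-variance input")
    stats::cor(av, bv)
}

## ---- SSIM -------------------------------------------------------------

.gaussKernel1d <- function(win, sigma) {
    x <- seq_len(win) - (win + 1) / 2
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

.validFilterMat <- function(n, k) {
    ## (n - w + 1) x n banded matrix applying kernel k by 'valid' convolution
    w <- length(k)
    M <- matrix(0, n - w + 1, n)
    for (i in seq_len(n - w + 1)) M[i, i + seq_len(w) - 1] <- k
    M
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma = 1.5), K1 = 0.01,
#' K2 = 0.03, computed over the valid interior and averaged. The data
#' range must be given explicitly (CT: 2047, the clip-window span; MRI:
#' the per-volume range).
#'
#' @param a,b numeric matrices of identical shape.
#' @param dataRange dynamic range of the data.
#' @param win window size (odd, default 11; shrunk for tiny images).
#' @param sigma Gaussian window SD (default 1.5).
#' @return SSIM in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(a, b, dataRange, win = 11L, sigma = 1.5) {
    if (!all(dim(a) == dim(b))) stop("shape mismatch")
    win <- min(win, dim(a))
    if (win %% 2L == 0L) win <- win - 1L
    k <- .gaussKernel1d(win, sigma)
    Bh <- .validFilterMat(nrow(a), k)
    Bw <- .validFilterMat(ncol(a), k)
    f <- function(m) Bh %*% m %*% t(Bw)
    C1 <- (0.01 * dataRange)^2
    C2 <- (0.03 * dataRange)^2
    mx <- f(a); my <- f(b)
    sxx <- f(a * a) - mx^2
    syy <- f(b * b) - my^2
    sxy <- f(a * b) - mx * my
    num <- (2 * mx * my + C1) * (2 * sxy + C2)
    den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
    mean(num / den)
}

## ---- FSIM -------------------------------------------------------------

.fftFreq <- function(n) (((seq_len(n) - 1 + floor(n / 2)) %% n) -
                             floor(n / 2)) / n

## Phase congruency (log-Gabor filter bank, 4 scales x 4 orientations,
## with noise-energy compensation and frequency-spread weighting).
.phaseCongruency <- function(im, nscale = 4L, norient = 4L,
                             minWaveLength = 6, mult = 2, sigmaOnf = 0.55,
                             k = 2, cutOff = 0.5, g = 10) {
    h <- nrow(im); w <- ncol(im)
    eps <- 1e-4
    fx <- matrix(.fftFreq(w), h, w, byrow = TRUE)
    fy <- matrix(.fftFreq(h), h, w)
    radius <- sqrt(fx^2 + fy^2)
    radius[1, 1] <- 1
    theta <- atan2(-fy, fx)
    sintheta <- sin(theta); costheta <- cos(theta)
    lp <- 1 / (1 + (radius / 0.45)^(2 * 15))
    logGabor <- vector("list", nscale)
    for (s in seq_len(nscale)) {
        f0 <- 1 / (minWaveLength * mult^(s - 1))
        lg <- exp(-(log(radius / f0))^2 / (2 * log(sigmaOnf)^2)) * lp
        lg[1, 1] <- 0
        logGabor[[s]] <- lg
    }
    thetaSigma <- pi / norient / 1.2
    IM <- stats::fft(im)
    pcNum <- matrix(0, h, w)
    pcDen <- matrix(0, h, w)
    for (o in seq_len(norient)) {
        angl <- (o - 1) * pi / norient
        ds <- sintheta * cos(angl) - costheta * sin(angl)
        dc <- costheta * cos(angl) + sintheta * sin(angl)
        dtheta <- abs(atan2(ds, dc))
        spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
        sumE <- matrix(0, h, w); sumO <- matrix(0, h, w)
        sumAn <- matrix(0, h, w); maxAn <- matrix(0, h, w)
        eList <- vector("list", nscale); oList <- vector("list", nscale)
        tau <- 0
        for (s in seq_len(nscale)) {
            filt <- logGabor[[s]] * spread
            EO <- stats::fft(IM * filt, inverse = TRUE) / (h * w)
            e <- Re(EO); oo <- Im(EO)
            An <- sqrt(e^2 + oo^2)
            sumAn <- sumAn + An
            sumE <- sumE + e; sumO <- sumO + oo
            maxAn <- pmax(maxAn, An)
            eList[[s]] <- e; oList[[s]] <- oo
            if (s == 1) tau <- stats::median(An) / sqrt(log(4))
        }
        xEnergy <- sqrt(sumE^2 + sumO^2) + eps
        meanE <- sumE / xEnergy; meanO <- sumO / xEnergy
        energy <- matrix(0, h, w)
        for (s in seq_len(nscale)) {
            e <- eList[[s]]; oo <- oList[[s]]
            energy <- energy + e * meanE + oo * meanO -
                abs(e * meanO - oo * meanE)
        }
        totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
        noiseMean <- totalTau * sqrt(pi / 2)
        noiseSigma <- totalTau * sqrt((4 - pi) / 2)
        T <- noiseMean + k * noiseSigma
        energy <- pmax(energy - T, 0)
        width <- (sumAn / (maxAn + eps)) / nscale
        weight <- 1 / (1 + exp(g * (cutOff - width)))
        pcNum <- pcNum + weight * energy
        pcDen <- pcDen + sumAn
    }
    pcNum / (pcDen + eps)
}

.scharrGradMag <- function(m) {
    kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
    gx <- .conv3x3(m, kx)
    gy <- .conv3x3(m, t(kx))
    sqrt(gx^2 + gy^2)
}

#' Feature similarity index (FSIM)
#'
#' Phase-congruency + gradient-magnitude feature similarity: local phase
#' congruency is computed with a log-Gabor bank (4 scales from wavelength
#' 6 with multiplier 2, 4 orientations, sigmaOnf 0.55, noise compensation
#' factor k = 2) and gradients with the Scharr operator; the similarity
#' map \code{S_PC^a * S_G^b} (a = b = 1, T1 = 0.85, T2 = 160 on a 0..255
#' scale) is averaged with phase-congruency weighting. Inputs are rescaled
#' jointly to 0..255 using \code{dataRange}; images larger than ~512 are
#' average-pooled first.
#'
#' @param a,b numeric matrices of identical shape (reference, test).
#' @param dataRange dynamic range used to map both images to 0..255
#'   (default: range of the pooled data).
#' @return FSIM in [0, 1]; 1 for identical images.
#' @export
fsim <- function(a, b, dataRange = NULL) {
    if (!all(dim(a) == dim(b))) stop("shape mismatch")
    if (is.null(dataRange)) {
        lo <- min(a, b); hi <- max(a, b)
        if (hi == lo) return(1)
        a <- (a - lo) / (hi - lo) * 255
        b <- (b - lo) / (hi - lo) * 255
    } else {
        lo <- min(a, b)
        a <- (a - lo) / dataRange * 255
        b <- (b - lo) / dataRange * 255
    }
    F <- max(1, round(min(dim(a)) / 256))
    if (F > 1) {
        pool <- function(m) {
            h <- (nrow(m) %/% F) * F; w <- (ncol(m) %/% F) * F
            m <- m[seq_len(h), seq_len(w)]
            dim(m) <- c(F, h / F, F, w / F)
            apply(m, c(2, 4), mean)
        }
        a <- pool(a); b <- pool(b)
    }
    pc1 <- .phaseCongruency(a)
    pc2 <- .phaseCongruency(b)
    g1 <- .scharrGradMag(a)
    g2 <- .scharrGradMag(b)
    T1 <- 0.85; T2 <- 160
    sPC <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
    sG <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
    pcm <- pmax(pc1, pc2)
    sum(sPC * sG * pcm) / sum(pcm)
}

## ---- Canny edges, EPR / EGR -------------------------------------------

## Separable Gaussian blur with replicate borders; exact (non-FFT) so
## that symmetric inputs stay symmetric to the last bit, which keeps the
## non-maximum-suppression tie-break deterministic.
.gaussBlurReplicate <- function(m, sigma) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-(-r:r)^2 / (2 * sigma^2))
    k <- k / sum(k)
    h <- nrow(m); w <- ncol(m)
    mp <- m[c(rep(1L, r), seq_len(h), rep(h, r)),
            c(rep(1L, r), seq_len(w), rep(w, r))]
    .validFilterMat(h + 2L * r, k) %*% mp %*%
        t(.validFilterMat(w + 2L * r, k))
}

.canny <- function(m, sigma = 1, lowFrac = 0.1, highFrac = 0.2) {
    if (sigma > 0) m <- .gaussBlurReplicate(m, sigma)
    gx <- .conv3x3(m, .sobelX)
    gy <- .conv3x3(m, .sobelY)
    mag <- sqrt(gx^2 + gy^2)
    h <- nrow(m); w <- ncol(m)
    ## flat images: gradient indistinguishable from round-off noise
    if (max(mag) <= 1e-10 * max(abs(m), 1)) return(matrix(FALSE, h, w))
    ## non-maximum suppression along the quantized gradient direction
    ## gx is the row-direction gradient, gy the column-direction one;
    ## sector 0 therefore steps along rows, sector 2 along columns
    ang <- atan2(gy, gx)
    sector <- (round(ang / (pi / 4)) %% 4)
    off <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(-1, 1))
    magP <- matrix(0, h + 2, w + 2)
    magP[2:(h + 1), 2:(w + 1)] <- mag
    ii <- 2:(h + 1); jj <- 2:(w + 1)
    nms <- matrix(FALSE, h, w)
    for (s in 0:3) {
        d <- off[[as.character(s)]]
        n1 <- magP[ii + d[1], jj + d[2], drop = FALSE]
        n2 <- magP[ii - d[1], jj - d[2], drop = FALSE]
        ## strict on one side so ties along a symmetric ridge keep one line
        keep <- (sector == s) & (mag > n1) & (mag >= n2)
        nms <- nms | keep
    }
    ## hysteresis thresholds as fractions of the gradient-magnitude maximum
    high <- highFrac * max(mag)
    low <- lowFrac * max(mag)
    strong <- nms & (mag >= high)
    weak <- nms & (mag >= low)
    if (!any(strong)) return(matrix(FALSE, h, w))
    lab <- EBImage::bwlabel(weak * 1)
    keepLabs <- unique(lab[strong])
    array(lab %in% setdiff(keepLabs, 0) & weak, c(h, w))
}

#' Binary Canny edge maps of an image pair
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression, and
#' hysteresis with low/high thresholds at fixed fractions of the
#' gradient-magnitude maximum; identical parameters are applied to both
#' images, and the parameters are recorded in the result.
#'
#' @param a reference (original) image matrix.
#' @param b test (generated) image matrix.
#' @param sigma Gaussian smoothing SD (default 1).
#' @param lowFrac,highFrac hysteresis thresholds as fractions of the
#'   maximum gradient magnitude (defaults 0.1 / 0.2).
#' @return List with logical matrices \code{original}, \code{generated}
#'   and the \code{params} used.
#' @export
edgeMaps <- function(a, b, sigma = 1, lowFrac = 0.1, highFrac = 0.2) {
    if (!all(dim(a) == dim(b))) stop("shape mismatch")
    list(original = .canny(a, sigma, lowFrac, highFrac),
         generated = .canny(b, sigma, lowFrac, highFrac),
         params = list(sigma = sigma, lowFrac = lowFrac,
                       highFrac = highFrac))
}

#' Edge generation ratio
#'
#' Ratio of edge-pixel counts, generated over original: values near 1
#' mean few spurious edges were introduced.
#'
#' @param maps edge maps from [edgeMaps()].
#' @return \code{num(generated) / num(original)}.
#' @export
egr <- function(maps) {
    n0 <- sum(maps$original)
    if (n0 == 0) stop("EGR undefined: original edge map is empty")
    sum(maps$generated) / n0
}

#' Edge preservation ratio
#'
#' Fraction of original edge pixels that survive in the generated image:
#' \code{num(original & generated) / num(original)}, in [0, 1].
#'
#' @inheritParams egr
#' @return Preservation ratio in [0, 1].
#' @export
epr <- function(maps) {
    n0 <- sum(maps$original)
    if (n0 == 0) stop("EPR undefined: original edge map is empty")
    sum(maps$original & maps$generated) / n0
}

## ---- LPIPS (pluggable) ------------------------------------------------

#' Perceptual distance on center patches (pluggable backend)
#'
#' Extracts the center 256 x 256 patch at the same spatial position from
#' both slices (center-padding smaller slices with the minimum value) and
#' evaluates the supplied perceptual backend on the pair. Lower values
#' mean greater perceptual similarity. Without a backend the metric is
#' reported as unavailable (\code{NA}), not an error: no feature-network
#' weights are shipped.
#'
#' @param a,b slice matrices of identical shape.
#' @param backend a \code{function(patchA, patchB) -> scalar}, or
#'   \code{NULL}.
#' @param size center patch side (default 256).
#' @return Backend distance, or \code{NA_real_} when no backend is given.
#' @export
lpipsCenter <- function(a, b, backend = NULL, size = 256L) {
    if (!all(dim(a) == dim(b))) stop("shape mismatch")
    if (is.null(backend)) return(NA_real_)
    crop <- function(m) {
        h <- nrow(m); w <- ncol(m)
        if (h < size || w < size) {
            out <- matrix(min(m), max(h, size), max(w, size))
            r0 <- (nrow(out) - h) %/% 2; c0 <- (ncol(out) - w) %/% 2
            out[r0 + seq_len(h), c0 + seq_len(w)] <- m
            m <- out; h <- nrow(m); w <- ncol(m)
        }
        r0 <- (h - size) %/% 2; c0 <- (w - size) %/% 2
        m[r0 + seq_len(size), c0 + seq_len(size)]
    }
    backend(crop(a), crop(b))
}

## ---- channel MAE ------------------------------------------------------

#' Per-channel MAE (air / bone / soft tissue)
#'
#' Splits the reference CT into three channels by thresholding (air below
#' \code{airBelow} HU, bone above \code{boneAbove} HU, soft tissue
#' otherwise) and reports the MAE of the synthetic CT restricted to each
#' channel. Empty channels give \code{NA}.
#'
#' @param sct synthetic-CT \linkS4class{ScanVolume} (or array).
#' @param refCT reference CT \linkS4class{ScanVolume} (or array) used for
#'   thresholding and comparison.
#' @param airBelow,boneAbove channel thresholds in HU (defaults -200 /
#'   +200).
#' @return Named numeric: \code{air}, \code{bone}, \code{soft},
#'   \code{total}.
#' @export
channelMAE <- function(sct, refCT, airBelow = -200, boneAbove = 200) {
    s <- if (is(sct, "ScanVolume")) voxelData(sct) else sct
    r <- if (is(refCT, "ScanVolume")) voxelData(refCT) else refCT
    if (!all(dim(s) == dim(r))) stop("shape mismatch")
    airM <- r < airBelow
    boneM <- r > boneAbove
    softM <- !airM & !boneM
    one <- function(m) if (!any(m)) NA_real_ else mean(abs(s - r)[m])
    c(air = one(airM), bone = one(boneM), soft = one(softM),
      total = mean(abs(s - r)))
}

## ---- slice-wise paired report -----------------------------------------

#' PairedReport: slice-wise paired metric report
#'
#' @slot perSlice data.frame of per-slice metric values.
#' @slot summary data.frame with mean and SD per metric (the "Average
#'   +/- St. Dev" convention).
#' @slot params list of metric parameters used (for reproducibility).
#' @exportClass PairedReport
setClass("PairedReport",
    representation(perSlice = "data.frame", summary = "data.frame",
                   params = "list"))

setMethod("show", "PairedReport", function(object) {
    cat("PairedReport over", nrow(object@perSlice), "slices:\n")
    s <- object@summary
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %-6s %.4g +/- %.4g\n", s$metric[i], s$mean[i],
                    s$sd[i]))
})

#' Slice-wise paired evaluation of a generated volume
#'
#' Computes MAE, SSIM, FSIM, EPR, EGR (and LPIPS when a backend is
#' supplied, PSNR/NCC/RMSE always) for every axial slice pair and
#' summarizes them as mean +/- SD, the aggregation used for whole-volume
#' reporting. Slices whose original edge map is empty are excluded from
#' the EPR/EGR averages (their count is recorded in \code{params}).
#'
#' @param gen generated \linkS4class{ScanVolume}.
#' @param ref reference \linkS4class{ScanVolume} (same geometry).
#' @param dataRange dynamic range for SSIM/PSNR (default 2047 for CT,
#'   per-volume range otherwise).
#' @param lpipsBackend optional perceptual backend for [lpipsCenter()].
#' @param mask optional \linkS4class{BodyMask}: restricts MAE to the body.
#' @param canny list of Canny parameters (see [edgeMaps()]).
#' @return A \linkS4class{PairedReport}.
#' @export
pairedReport <- function(gen, ref, dataRange = NULL, lpipsBackend = NULL,
                         mask = NULL,
                         canny = list(sigma = 1, lowFrac = 0.1,
                                      highFrac = 0.2)) {
    ga <- voxelData(gen); ra <- voxelData(ref)
    if (!all(dim(ga) == dim(ra))) stop("volume geometries differ")
    if (is.null(dataRange))
        dataRange <- if (modality(ref) == "CT") 2047 else diff(range(ra))
    d <- dim(ga)
    m <- if (is.null(mask)) NULL else voxelData(mask)
    rows <- vector("list", d[1])
    emptyEdges <- 0L
    for (k in seq_len(d[1])) {
        g2 <- array(ga[k, , ], d[2:3]); r2 <- array(ra[k, , ], d[2:3])
        em <- edgeMaps(r2, g2, canny$sigma, canny$lowFrac, canny$highFrac)
        if (sum(em$original) == 0) {
            eprV <- NA_real_; egrV <- NA_real_
            emptyEdges <- emptyEdges + 1L
        } else {
            eprV <- epr(em); egrV <- egr(em)
        }
        nccV <- if (stats::sd(as.vector(r2)) == 0 ||
                    stats::sd(as.vector(g2)) == 0) NA_real_ else ncc(r2, g2)
        rows[[k]] <- data.frame(
            slice = k,
            mae = if (is.null(m)) mae(g2, r2)
                  else mae(g2, r2, array(m[k, , ], d[2:3])),
            ssim = ssim(g2, r2, dataRange),
            fsim = fsim(r2, g2, dataRange),
            epr = eprV, egr = egrV,
            lpips = lpipsCenter(r2, g2, lpipsBackend),
            psnr = psnr(g2, r2, dataRange),
            ncc = nccV,
            rmse = rmse(g2, r2))
    }
    perSlice <- do.call(rbind, rows)
    metrics <- setdiff(names(perSlice), "slice")
    summary <- data.frame(
        metric = metrics,
        mean = vapply(metrics, function(mm)
            mean(perSlice[[mm]], na.rm = TRUE), numeric(1)),
        sd = vapply(metrics, function(mm)
            stats::sd(perSlice[[mm]], na.rm = TRUE), numeric(1)),
        row.names = NULL)
    new("PairedReport", perSlice = perSlice, summary = summary,
        params = list(dataRange = dataRange, canny = canny,
                      emptyEdgeSlices = emptyEdges,
                      lpipsAvailable = !is.null(lpipsBackend)))
}
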