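## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately written as plain loops so they stay independent of the
## package's vectorized implementations.

## A CT slice holding a soft-tissue disk on an air background.
diskSlice <- function(n = 96, radius = 28, value = 40, bg = -1000,
                      center = c(n / 2, n / 2)) {
    m <- matrix(bg, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        if ((i - center[1])^2 + (j - center[2])^2 <= radius^2)
            m[i, j] <- value
    m
}

## Small unpaired training domains: shifted piecewise-constant phantoms
## vs noisy counterparts, all 64 x 64 in [-1, 1].
smokeDomains <- function(nX = 16, nY = 16, seed = 11) {
    set.seed(seed)
    base <- matrix(-1, 64, 64)
    base[20:44, 16:48] <- 0.2
    base[28:36, 28:36] <- 0.6
    dx <- lapply(seq_len(nX), function(i) {
        sh <- (i %% 5) - 2
        m <- base
        if (sh != 0) m <- m[pmin(pmax(seq_len(64) + sh, 1), 64), ]
        m
    })
    dy <- lapply(seq_len(nY), function(i)
        pmin(pmax(base + matrix(rnorm(64 * 64, 0, 0.15), 64), -1), 1))
    list(x = dx, y = dy)
}

## Brute-force metric oracles ------------------------------------------

oracleMAE <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
    s / length(a)
}

oracleRMSE <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
    sqrt(s / length(a))
}

oracleNCC <- function(a, b) {
    av <- as.vector(a); bv <- as.vector(b)
    ma <- sum(av) / length(av); mb <- sum(bv) / length(bv)
    num <- sum((av - ma) * (bv - mb))
    num / sqrt(sum((av - ma)^2) * sum((bv - mb)^2))
}

oraclePSNR <- function(a, b, dataRange) {
    mse <- sum((a - b)^2) / length(a)
    20 * log10(dataRange) - 10 * log10(mse)
}

## Direct windowed-loop SSIM (valid windows, Gaussian weights).
oracleSSIM <- function(a, b, dataRange, win = 11, sigma = 1.5) {
    x <- seq_len(win) - (win + 1) / 2
    k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
    K <- outer(k1, k1)
    C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
    H <- nrow(a) - win + 1; W <- ncol(a) - win + 1
    vals <- numeric(0)
    for (i in seq_len(H)) for (j in seq_len(W)) {
        wa <- a[i + seq_len(win) - 1, j + seq_len(win) - 1]
        wb <- b[i + seq_len(win) - 1, j + seq_len(win) - 1]
        mx <- sum(K * wa); my <- sum(K * wb)
        vx <- sum(K * wa^2) - mx^2
        vy <- sum(K * wb^2) - my^2
        cxy <- sum(K * wa * wb) - mx * my
        vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                      ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
    mean(vals)
}

## Independent FSIM reimplementation: same definition, separately coded
## (explicit per-pixel filter construction, loop-accumulated bank).
oracleFSIM <- function(a, b, dataRange = NULL) {
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
    h <- nrow(a); w <- ncol(a)
    freqOf <- function(n) {
        f <- numeric(n)
        for (i in seq_len(n))
            f[i] <- (((i - 1 + floor(n / 2)) %% n) - floor(n / 2)) / n
        f
    }
    fy <- freqOf(h); fx <- freqOf(w)
    rad <- matrix(0, h, w); th <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
        rad[i, j] <- sqrt(fy[i]^2 + fx[j]^2)
        th[i, j] <- atan2(-fy[i], fx[j])
    }
    rad[1, 1] <- 1
    lp <- 1 / (1 + (rad / 0.45)^30)
    pcOf <- function(im) {
        IM <- fft(im)
        nscale <- 4; norient <- 4
        thetaSigma <- pi / norient / 1.2
        pcN <- matrix(0, h, w); pcD <- matrix(0, h, w)
        for (o in seq_len(norient)) {
            angl <- (o - 1) * pi / norient
            dth <- abs(atan2(sin(th) * cos(angl) - cos(th) * sin(angl),
                             cos(th) * cos(angl) + sin(th) * sin(angl)))
            spread <- exp(-dth^2 / (2 * thetaSigma^2))
            sumE <- 0; sumO <- 0; sumAn <- 0; maxAn <- 0
            es <- list(); os <- list(); tau <- 0
            for (s in seq_len(nscale)) {
                f0 <- 1 / (6 * 2^(s - 1))
                lg <- exp(-(log(rad / f0))^2 / (2 * log(0.55)^2)) * lp
                lg[1, 1] <- 0
                EO <- fft(IM * lg * spread, inverse = TRUE) / (h * w)
                e <- Re(EO); oo <- Im(EO)
                An <- sqrt(e^2 + oo^2)
                sumE <- sumE + e; sumO <- sumO + oo
                sumAn <- sumAn + An; maxAn <- pmax(maxAn, An)
                es[[s]] <- e; os[[s]] <- oo
                if (s == 1) tau <- median(An) / sqrt(log(4))
            }
            xE <- sqrt(sumE^2 + sumO^2) + 1e-4
            mE <- sumE / xE; mO <- sumO / xE
            energy <- 0
            for (s in seq_len(nscale))
                energy <- energy + es[[s]] * mE + os[[s]] * mO -
                    abs(es[[s]] * mO - os[[s]] * mE)
            tt <- tau * (1 - (1 / 2)^nscale) / (1 - 1 / 2)
            T <- tt * sqrt(pi / 2) + 2 * tt * sqrt((4 - pi) / 2)
            energy <- pmax(energy - T, 0)
            wdt <- (sumAn / (maxAn + 1e-4)) / nscale
            wt <- 1 / (1 + exp(10 * (0.5 - wdt)))
            pcN <- pcN + wt * energy
            pcD <- pcD + sumAn
        }
        pcN / (pcD + 1e-4)
    }
    gradOf <- function(m) {
        kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
        gx <- matrix(0, h, w); gy <- matrix(0, h, w)
        for (i in seq_len(h)) for (j in seq_len(w)) {
            sx <- 0; sy <- 0
            for (di in -1:1) for (dj in -1:1) {
                ii <- min(max(i + di, 1), h); jj <- min(max(j + dj, 1), w)
                sx <- sx + kx[di + 2, dj + 2] * m[ii, jj]
                sy <- sy + kx[dj + 2, di + 2] * m[ii, jj]
            }
            gx[i, j] <- sx; gy[i, j] <- sy
        }
        sqrt(gx^2 + gy^2)
    }
    pc1 <- pcOf(a); pc2 <- pcOf(b)
    g1 <- gradOf(a); g2 <- gradOf(b)
    sPC <- (2 * pc1 * pc2 + 0.85) / (pc1^2 + pc2^2 + 0.85)
    sG <- (2 * g1 * g2 + 160) / (g1^2 + g2^2 + 160)
    pcm <- pmax(pc1, pc2)
    sum(sPC * sG * pcm) / sum(pcm)
}

oracleHistCC <- function(va, vb, breaks) {
    dens <- function(x) {
        cnt <- numeric(length(breaks) - 1)
        for (v in x) {
            for (bi in seq_len(length(breaks) - 1)) {
                if (v >= breaks[bi] &&
                    (v < breaks[bi + 1] ||
                     (bi == length(breaks) - 1 && v <= breaks[bi + 1]))) {
                    cnt[bi] <- cnt[bi] + 1
                    break
                }
            }
        }
        cnt / sum(cnt)
    }
    ha <- dens(va); hb <- dens(vb)
    oracleNCC(ha, hb)
}
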