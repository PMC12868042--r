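test_that("noise magnitude has its closed-form values", {
    v <- array(7, c(2, 10, 10))
    m <- array(TRUE, c(2, 10, 10))
    expect_equal(noiseMagnitude(v, m), 0)
    ## two-value organ {0, 2} equally -> population SD 1
    v2 <- array(rep(c(0, 2), 50), c(1, 10, 10))
    expect_equal(noiseMagnitude(v2, array(TRUE, c(1, 10, 10))), 1)
    expect_error(noiseMagnitude(v, array(FALSE, c(2, 10, 10))), "empty")
    ## Gaussian organ recovers sigma within 5% at n = 10^4
    set.seed(50)
    v3 <- array(100 + rnorm(1e4, 0, 20), c(4, 50, 50))
    expect_lt(abs(noiseMagnitude(v3, array(TRUE, c(4, 50, 50))) - 20) / 20,
              0.05)
})

test_that("radial NPS separates white from low-pass noise textures", {
    set.seed(51)
    ## zero-noise ROI -> zero curve
    z <- radialNPS(array(3, c(4, 32, 32)))
    expect_true(all(z$power == 0))
    ## white noise -> flat curve (max/min bin ratio < 2 over 20 slices)
    roi <- array(rnorm(64 * 64 * 20), c(20, 64, 64))
    cw <- radialNPS(roi)
    expect_lt(max(cw$power) / min(cw$power), 2)
    ## blurred noise -> decreasing power beyond the first bins
    blur <- roi
    for (k in 1:20)
        blur[k, , ] <- EBImage::gblur(array(roi[k, , ], c(64, 64)),
                                      sigma = 2)
    cb <- radialNPS(blur)
    lowBand <- mean(cb$power[2:6])
    highBand <- mean(cb$power[(nrow(cb) - 5):nrow(cb)])
    expect_gt(lowBand / highBand, 10)
    expect_error(radialNPS(array(0, c(2, 8, 8))), "16 x 16")
})

test_that("total NPS power tracks the detrended voxel variance", {
    set.seed(52)
    roi <- array(rnorm(48 * 48 * 10, 0, 5), c(10, 48, 48))
    ## Parseval: sum of the 2D spectrum equals variance * dx * dy; the
    ## radial average preserves this within binning error
    cw <- radialNPS(roi, spacing = c(1, 1, 1), nbins = 24)
    ## Parseval sanity on a flat (white) spectrum: the count-weighted mean
    ## spectral density equals dx*dy*variance of the detrended slices
    d <- c(48, 48)
    fr <- matrix(phantomForge:::.fftFreq(d[1]), d[1], d[2])
    fc <- matrix(phantomForge:::.fftFreq(d[2]), d[1], d[2], byrow = TRUE)
    rad <- sqrt(fr^2 + fc^2)
    edges <- seq(0, 0.5, length.out = 25)
    bin <- findInterval(rad, edges, rightmost.closed = TRUE)
    counts <- tabulate(bin[bin >= 1 & bin <= 24 & rad > 0], 24)
    total <- sum(cw$power * counts[seq_len(nrow(cw))]) / sum(counts)
    vhat <- mean(apply(roi, 1, function(s) mean((s - mean(s))^2)))
    expect_lt(abs(total - vhat) / vhat, 0.1)
})

test_that("NPS curve correlation is affine-invariant Pearson", {
    set.seed(53)
    c1 <- data.frame(freq = seq(0.01, 0.5, length.out = 20),
                     power = runif(20))
    expect_equal(npsCorrelation(c1, c1), 1)
    c2 <- c1; c2$power <- 3 * c1$power + 0.7
    expect_equal(npsCorrelation(c1, c2), 1)
    c3 <- c1; c3$power <- rev(c1$power)
    expect_lt(npsCorrelation(c1, c3), 1)
    c4 <- c1[1:10, ]
    expect_error(npsCorrelation(c1, c4), "binning")
})

test_that("cohort histogram correlation matches a hand-computed 4-bin case", {
    ## disjoint-support uniform histograms -> negative correlation
    va <- c(0.5, 0.5, 1.5, 1.5)     # occupies bins 1-2 of [0,4]
    vb <- c(2.5, 2.5, 3.5, 3.5)     # occupies bins 3-4
    breaks <- 0:4
    a <- ScanVolume(array(va, c(1, 2, 2)))
    b <- ScanVolume(array(vb, c(1, 2, 2)))
    got <- histCorrelation(list(a), list(b), breaks = breaks)
    expect_equal(got, oracleHistCC(va, vb, breaks), tolerance = 1e-12)
    expect_lt(got, 0)
    ## identical cohorts with a non-degenerate histogram -> exactly 1
    set.seed(55)
    c0 <- ScanVolume(array(rbeta(200, 2, 5) * 4, c(2, 10, 10)))
    expect_equal(histCorrelation(list(a, c0), list(a, c0),
                                 breaks = breaks), 1)
    ## invariant to volume order within cohorts and to cohort order
    set.seed(54)
    c1 <- ScanVolume(array(runif(200, 0, 4), c(2, 10, 10)))
    c2 <- ScanVolume(array(runif(200, 0, 4), c(2, 10, 10)))
    d1 <- ScanVolume(array(runif(200, 0, 4), c(2, 10, 10)))
    h12 <- histCorrelation(list(c1, c2), list(d1), breaks = breaks)
    h21 <- histCorrelation(list(c2, c1), list(d1), breaks = breaks)
    expect_equal(h12, h21)
    expect_equal(histCorrelation(list(d1), list(c1, c2), breaks = breaks),
                 h12)
    expect_error(histCorrelation(list(), list(a)), "non-empty")
})

test_that("ROI placement finds a fully enclosed box inside an organ", {
    lab <- makeLabels(PhantomSpec(gridDim = c(12L, 64L, 64L), seed = 1L))
    roi <- largestBoxROI(lab, size = c(4L, 10L, 10L), label = 4L)
    sub <- extractROI(voxelData(lab), roi$origin, roi$size)
    expect_true(all(sub == 4L))
    expect_error(largestBoxROI(array(FALSE, c(4, 8, 8)),
                               size = c(2L, 4L, 4L)), "no fully enclosed")
})
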