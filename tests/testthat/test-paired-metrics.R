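test_that("scalar metrics agree with brute-force loop oracles", {
    set.seed(40)
    for (rep in 1:5) {
        a <- matrix(rnorm(32 * 32), 32)
        b <- matrix(rnorm(32 * 32), 32)
        expect_equal(mae(a, b), oracleMAE(a, b), tolerance = 1e-6)
        expect_equal(rmse(a, b), oracleRMSE(a, b), tolerance = 1e-6)
        expect_equal(ncc(a, b), oracleNCC(a, b), tolerance = 1e-6)
        expect_equal(psnr(a, b, 4), oraclePSNR(a, b, 4), tolerance = 1e-6)
        expect_equal(ssim(a, b, dataRange = 4),
                     oracleSSIM(a, b, dataRange = 4), tolerance = 1e-6)
    }
})

test_that("metric identities and symmetries hold", {
    set.seed(41)
    a <- matrix(rnorm(400), 20)
    expect_equal(mae(a, a), 0)
    expect_equal(mae(a, a + 5), 5)
    expect_equal(rmse(a, a), 0)
    expect_equal(rmse(a, a + 3), 3, tolerance = 1e-12)
    expect_equal(ncc(a, a), 1)
    expect_equal(ncc(a, 2 * a + 3), 1)           # affine invariance
    expect_equal(psnr(a, a, 4), Inf)
    expect_error(ncc(a, matrix(1, 20, 20)), "zero-variance")
    b <- matrix(rnorm(400), 20)
    expect_equal(mae(a, b), mae(b, a))
    expect_equal(rmse(a, b), rmse(b, a))
    expect_equal(ssim(a, b, 4), ssim(b, a, 4), tolerance = 1e-12)
    expect_equal(ncc(a, b), ncc(b, a))
})

test_that("SSIM is 1 for identical images and penalizes differences", {
    set.seed(42)
    a <- matrix(rnorm(32 * 32), 32)
    expect_equal(ssim(a, a, dataRange = 4), 1, tolerance = 1e-9)
    ## contrast inversion: a high-frequency zero-mean pattern (local means
    ## vanish, so the structure term dominates and flips the sign)
    alt <- outer(rep(1, 32), rep(c(1, -1), 16)) * 0.5
    expect_lt(ssim(alt, -alt, dataRange = 4), 0)
    ## luminance term decreases with a growing constant offset
    base <- matrix(1, 16, 16)
    vals <- vapply(c(0.1, 0.3, 0.6), function(d)
        ssim(base, base + d, dataRange = 1), numeric(1))
    expect_true(all(vals < 1))
    expect_true(all(diff(vals) < 0))
})

test_that("FSIM matches an independent reimplementation to 1e-3", {
    set.seed(43)
    for (rep in 1:3) {
        a <- matrix(rnorm(64 * 64), 64)
        b <- a + matrix(rnorm(64 * 64, 0, 0.5), 64)
        expect_equal(fsim(a, b), oracleFSIM(a, b), tolerance = 1e-3)
    }
    a <- matrix(rnorm(64 * 64), 64)
    expect_equal(fsim(a, a), 1, tolerance = 1e-9)
    n1 <- matrix(rnorm(64 * 64), 64)
    n2 <- matrix(rnorm(64 * 64), 64)
    expect_lt(fsim(n1, n2), 1)
})

test_that("Canny edge maps behave on canonical fixtures", {
    expect_false(any(edgeMaps(matrix(1, 32, 32),
                              matrix(1, 32, 32))$original))
    ## vertical step edge -> a single one-pixel-wide vertical line
    step <- matrix(0, 40, 40); step[, 21:40] <- 100
    em <- edgeMaps(step, step)$original
    nzCols <- which(colSums(em[5:35, ]) > 0)
    expect_equal(length(nzCols), 1L)
    ## same image twice -> identical maps
    set.seed(44)
    img <- diskSlice(48, 14)
    ems <- edgeMaps(img, img)
    expect_identical(ems$original, ems$generated)
})

test_that("edge ratios count pixels as defined", {
    mk <- function(o, g) list(original = o, generated = g)
    o <- matrix(FALSE, 5, 5); o[2, 1:4] <- TRUE           # 4 edge pixels
    g6 <- matrix(FALSE, 5, 5); g6[2, 1:4] <- TRUE; g6[4, 1:2] <- TRUE
    expect_equal(egr(mk(o, g6)), 1.5)                      # 6 / 4
    g2 <- matrix(FALSE, 5, 5); g2[2, 1:2] <- TRUE
    expect_equal(epr(mk(o, g2)), 0.5)                      # 2 of 4 kept
    expect_equal(epr(mk(o, o)), 1)
    expect_equal(egr(mk(o, o)), 1)
    disj <- matrix(FALSE, 5, 5); disj[5, 5] <- TRUE
    expect_equal(epr(mk(o, disj)), 0)
    empty <- matrix(FALSE, 5, 5)
    expect_error(epr(mk(empty, o)), "undefined")
    expect_error(egr(mk(empty, o)), "undefined")
    ## EPR/EGR are asymmetric by construction
    expect_false(isTRUE(all.equal(epr(mk(o, g2)), epr(mk(g2, o)))))
})

test_that("perceptual metric uses the pluggable backend on center patches", {
    set.seed(45)
    a <- matrix(rnorm(300 * 300), 300)
    expect_true(is.na(lpipsCenter(a, a, backend = NULL)))
    ## mock backend: normalized MSE on the 256 center patch
    mock <- function(pa, pb) mean((pa - pb)^2) / (sd(pa)^2 + 1e-12)
    expect_equal(lpipsCenter(a, a, backend = mock), 0)
    b <- a + 1
    ctr <- 22 + seq_len(256)
    direct <- mean((a[ctr, ctr] - b[ctr, ctr])^2) /
        (sd(a[ctr, ctr])^2 + 1e-12)
    expect_equal(lpipsCenter(a, b, backend = mock), direct,
                 tolerance = 1e-12)
    ## small slices are center-padded, not rejected
    small <- matrix(rnorm(100 * 100), 100)
    expect_equal(lpipsCenter(small, small, backend = mock), 0)
})

test_that("channel MAE isolates the thresholded compartments", {
    set.seed(46)
    ref <- array(c(rep(-800, 40), rep(0, 40), rep(500, 20)), c(1, 10, 10))
    expect_equal(unname(channelMAE(ref, ref)), c(0, 0, 0, 0))
    sct <- ref; sct[ref > 200] <- sct[ref > 200] + 30
    cm <- channelMAE(sct, ref)
    expect_equal(unname(cm["air"]), 0)
    expect_equal(unname(cm["bone"]), 30)
    expect_equal(unname(cm["soft"]), 0)
    ## empty bone channel reported missing
    soft <- array(0, c(1, 4, 4))
    expect_true(is.na(channelMAE(soft, soft)["bone"]))
})

test_that("volume reports aggregate slice metrics as mean +/- SD", {
    set.seed(47)
    base <- array(0, c(3, 48, 48))
    for (k in 1:3) base[k, , ] <- diskSlice(48, 10 + 2 * k)
    ref <- ScanVolume(base, modality = "CT")
    gen <- ScanVolume(base + array(rnorm(length(base), 0, 20), dim(base)),
                      modality = "CT")
    rep <- pairedReport(gen, ref)
    ps <- rep@perSlice
    expect_equal(nrow(ps), 3L)
    s <- rep@summary
    expect_equal(s$mean[s$metric == "mae"], mean(ps$mae))
    expect_equal(s$sd[s$metric == "ssim"], sd(ps$ssim))
    ## identical volumes -> perfect scores
    rep0 <- pairedReport(ref, ref)
    s0 <- rep0@summary
    expect_equal(s0$mean[s0$metric == "mae"], 0)
    expect_equal(s0$mean[s0$metric == "ssim"], 1, tolerance = 1e-9)
    expect_equal(s0$mean[s0$metric == "epr"], 1)
    expect_equal(s0$mean[s0$metric == "egr"], 1)
})
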