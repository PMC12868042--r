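test_that("origin lattice enumerates stride positions plus clamped edge", {
    expect_equal(patchOriginsForAxis(348, 220, 64), c(0L, 64L, 128L))
    expect_equal(patchOriginsForAxis(300, 220, 64), c(0L, 64L, 80L))
    expect_equal(patchOriginsForAxis(320, 200, 32),
                 c(0L, 32L, 64L, 96L, 120L))
    expect_equal(patchOriginsForAxis(260, 200, 32), c(0L, 32L, 60L))
    expect_equal(patchOriginsForAxis(256, 256, 32), 0L)
    expect_error(patchOriginsForAxis(100, 200, 32), "exceeds")
})

test_that("inference tiling yields the canonical 9-patch cover of 348", {
    g <- tileForInference(matrix(rnorm(348 * 348), 348), 220, 64)
    expect_equal(length(g), 9L)
    o <- patchOrigins(g)
    expect_setequal(unique(o[, "row0"]), c(0L, 64L, 128L))
    expect_setequal(unique(o[, "col0"]), c(0L, 64L, 128L))
    ## full coverage: every pixel covered at least once
    cov <- matrix(0, 348, 348)
    for (i in seq_len(nrow(o)))
        cov[o[i, 2] + 1:220, o[i, 3] + 1:220] <-
            cov[o[i, 2] + 1:220, o[i, 3] + 1:220] + 1
    expect_true(all(cov >= 1))
})

test_that("training extraction counts candidates and is seed-reproducible", {
    v <- ScanVolume(array(rnorm(2 * 320 * 260), c(2, 320, 260)))
    g <- extractTrainingPatches(v, 200, 32, perSlice = 100L, seed = 1L)
    expect_equal(length(g), 2L * 15L)      # 5 x 3 candidate lattice
    g1 <- extractTrainingPatches(v, 200, 32, perSlice = 4L, seed = 7L)
    g2 <- extractTrainingPatches(v, 200, 32, perSlice = 4L, seed = 7L)
    expect_identical(patchOrigins(g1), patchOrigins(g2))
    expect_identical(patchData(g1), patchData(g2))
    expect_equal(length(g1), 8L)
})

test_that("foreground filter drops background-dominated candidates", {
    arr <- array(0, c(1, 96, 96))
    m <- array(FALSE, c(1, 96, 96))
    m[1, 49:96, 49:96] <- TRUE            # body in lower-right quadrant
    v <- ScanVolume(arr)
    g <- extractTrainingPatches(v, 48, 48, perSlice = 10L, seed = 1L,
                                mask = BodyMask(m), minForeground = 0.9)
    o <- patchOrigins(g)
    expect_true(all(o[, "row0"] == 48L & o[, "col0"] == 48L))
})

test_that("bilinear patch resize is convex, identical at same size", {
    p <- matrix(3.5, 220, 220)
    expect_equal(resizePatch(p, 256), matrix(3.5, 256, 256))
    set.seed(5)
    q <- matrix(rnorm(64 * 64), 64)
    expect_identical(resizePatch(q, 64), q)
    r <- resizePatch(q, 96)
    expect_gte(min(r), min(q))
    expect_lte(max(r), max(q))
})

test_that("the 220 <-> 256 resize cycle keeps smooth images within 2% RMS", {
    i <- seq_len(220)
    blob <- exp(-outer((i - 110)^2, (i - 90)^2, "+") / (2 * 40^2))
    cyc <- resizePatch(resizePatch(blob, 256), 220)
    rms <- sqrt(mean((cyc - blob)^2)) / diff(range(blob))
    expect_lt(rms, 0.02)
})

test_that("mean fusion averages overlaps and inverts tiling exactly", {
    set.seed(6)
    sl <- matrix(rnorm(300 * 300), 300)
    g <- tileForInference(sl, 220, 64)
    expect_identical(fuseMean(g), sl)      # partition-of-unity identity
    ## constant patches fuse to the constant
    gc <- tileForInference(matrix(0, 120, 120), 80, 40)
    preds <- replicate(length(gc), matrix(4.2, 80, 80), simplify = FALSE)
    expect_equal(unique(as.vector(fuseMean(gc, preds))), 4.2)
    ## two overlapping patches valued 0 and 2 average to 1 in the overlap
    g2 <- tileForInference(matrix(0, 100, 60), 60, 40)  # rows {0, 40}
    expect_equal(length(g2), 2L)
    preds2 <- list(matrix(0, 60, 60), matrix(2, 60, 60))
    fused <- fuseMean(g2, preds2)
    expect_equal(unique(as.vector(fused[41:60, ])), 1)
    expect_equal(unique(as.vector(fused[1:40, ])), 0)
    expect_equal(unique(as.vector(fused[61:100, ])), 2)
    expect_error(fuseMean(g2, preds2[1]), "one prediction per patch")
})
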