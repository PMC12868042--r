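test_that("CT clipping clamps to [-1000, 1047] and is idempotent", {
    v <- ScanVolume(array(c(3000, -2000, 100, 0), c(1, 2, 2)),
                    modality = "CT")
    cl <- clipCT(v)
    expect_equal(sort(as.vector(voxelData(cl))), c(-1000, 0, 100, 1047))
    expect_equal(intensityRange(cl), c(-1000, 1047))
    expect_equal(voxelData(clipCT(cl)), voxelData(cl))
    ## in-range and all-air volumes are unchanged
    air <- ScanVolume(array(-1000, c(1, 2, 2)), modality = "CT")
    expect_equal(voxelData(clipCT(air)), voxelData(air))
    expect_error(clipCT(ScanVolume(array(0, c(1, 2, 2)))), "modality")
})

test_that("normalization maps the range endpoints and midpoint exactly", {
    v <- clipCT(ScanVolume(array(c(-1000, 1047, 23.5, 0), c(1, 2, 2)),
                           modality = "CT"))
    n <- normalizeVolume(v)
    x <- voxelData(n)
    expect_equal(x[1, 1, 1], -1)
    expect_equal(x[1, 2, 1], 1)
    expect_equal(x[1, 1, 2], 0)
    ## MRI midpoint with explicit range
    m <- ScanVolume(array(c(0, 200, 100, 50), c(1, 2, 2)), modality = "MRI",
                    intensityRange = c(0, 200))
    expect_equal(voxelData(normalizeVolume(m))[1, 1, 2], 0)
})

test_that("denormalize inverts normalize within float tolerance", {
    set.seed(3)
    v <- clipCT(ScanVolume(array(runif(4 * 6 * 6, -1000, 1047), c(4, 6, 6)),
                           modality = "CT"))
    round <- denormalizeVolume(normalizeVolume(v))
    expect_lt(max(abs(voxelData(round) - voxelData(v))), 2047 * 1e-4)
    ## endpoints of the inverse map
    n <- ScanVolume(array(c(-1, 1, 0, 0), c(1, 2, 2)), modality = "CT",
                    intensityRange = c(-1000, 1047))
    d <- voxelData(denormalizeVolume(n))
    expect_equal(d[1, 1, 1], -1000)
    expect_equal(d[1, 2, 1], 1047)
    expect_equal(d[1, 1, 2], 23.5)
    expect_error(denormalizeVolume(
        ScanVolume(array(0, c(1, 2, 2)))), "range")
})

test_that("degenerate intensity range is rejected", {
    v <- ScanVolume(array(5, c(1, 2, 2)), modality = "MRI")
    expect_error(normalizeVolume(v), "degenerate")
})

test_that("body mask recovers a disk within 1% and drops smaller components", {
    sl <- diskSlice(n = 96, radius = 28)
    v <- ScanVolume(array(sl, c(1, 96, 96)), modality = "CT")
    m <- bodyMask(clipCT(v))
    truth <- sl >= -110
    area <- sum(voxelData(m))
    expect_lt(abs(area - sum(truth)) / sum(truth), 0.01)
    ## two disks: only the larger is retained
    two <- diskSlice(96, 24)
    small <- diskSlice(96, 6, center = c(14, 14))
    two[small > -1000] <- 40
    m2 <- bodyMask(clipCT(ScanVolume(array(two, c(1, 96, 96)),
                                     modality = "CT")))
    expect_false(any(voxelData(m2)[1, 1:20, 1:20]))
    expect_true(any(voxelData(m2)[1, 40:60, 40:60]))
    ## uniform air slice -> empty mask, no error
    m3 <- bodyMask(clipCT(ScanVolume(array(-1000, c(1, 32, 32)),
                                     modality = "CT")))
    expect_equal(sum(voxelData(m3)), 0)
})

test_that("largest-component refinement is idempotent", {
    sl <- diskSlice(n = 64, radius = 20)
    v <- clipCT(ScanVolume(array(sl, c(1, 64, 64)), modality = "CT"))
    m1 <- bodyMask(v)
    masked <- applyBackground(v, m1)
    m2 <- bodyMask(masked)
    expect_equal(voxelData(m2), voxelData(m1))
})

test_that("background suppression fills outside the mask only", {
    set.seed(4)
    arr <- array(runif(2 * 8 * 8, -500, 500), c(2, 8, 8))
    v <- ScanVolume(arr, modality = "CT")
    full <- BodyMask(array(TRUE, dim(arr)))
    expect_equal(voxelData(applyBackground(v, full)), arr)
    empty <- BodyMask(array(FALSE, dim(arr)))
    expect_true(all(voxelData(applyBackground(v, empty)) == -1000))
    half <- array(FALSE, dim(arr)); half[, 1:4, ] <- TRUE
    out <- voxelData(applyBackground(v, BodyMask(half)))
    expect_identical(out[, 1:4, ], arr[, 1:4, ])
    expect_true(all(out[, 5:8, ] == -1000))
    ## MRI background is zero
    mv <- ScanVolume(arr, modality = "MRI")
    expect_true(all(voxelData(applyBackground(mv, empty)) == 0))
    expect_error(applyBackground(v, BodyMask(array(TRUE, c(1, 8, 8)))),
                 "shape")
})
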