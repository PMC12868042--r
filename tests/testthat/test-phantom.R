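test_that("label generation is deterministic and respects the organ set", {
    spec <- PhantomSpec(gridDim = c(10L, 64L, 64L), seed = 5L)
    l1 <- makeLabels(spec)
    l2 <- makeLabels(spec)
    expect_identical(voxelData(l1), voxelData(l2))
    ## no lungs requested -> no lung labels
    noLungs <- makeLabels(PhantomSpec(gridDim = c(10L, 64L, 64L),
                                      organs = c("body", "liver", "spine"),
                                      seed = 5L))
    expect_false(any(voxelData(noLungs) %in% c(2L, 3L)))
    ## liver contained in the body
    nLiver <- sum(voxelData(l1) == 4L)
    nBody <- sum(voxelData(l1) > 0L)
    expect_gt(nLiver, 0)
    expect_lt(nLiver, nBody)
})

test_that("attenuation-to-HU conversion follows the water definition", {
    expect_equal(muToHU(0.1615, 0.1615), 0)
    expect_equal(muToHU(0, 0.1615), -1000)
    expect_equal(muToHU(2 * 0.1615, 0.1615), 1000)
    expect_error(muToHU(0.1, 0), "positive")
})

test_that("rendered CT is piecewise constant with one value per label", {
    lab <- makeLabels(PhantomSpec(gridDim = c(8L, 48L, 48L), seed = 2L))
    tt <- defaultTissueTable()
    ct <- renderCT(lab, tt)
    present <- unique(as.vector(voxelData(lab)))
    huOf <- muToHU(tt@table$mu_120kev, tt@muWater)
    nDistinct <- length(unique(huOf[match(present, tt@table$label)]))
    expect_identical(length(unique(as.vector(voxelData(ct)))), nDistinct)
    expect_lte(nDistinct, length(present))   # left/right lung share one HU
    for (lv in setdiff(unique(as.vector(voxelData(lab))), 0L))
        expect_equal(sd(voxelData(ct)[voxelData(lab) == lv]), 0)
    expect_true(all(voxelData(ct)[voxelData(lab) == 0L] == -1000))
    ## all-background label map renders to pure air
    empty <- LabelVolume(array(0L, c(2, 8, 8)))
    expect_true(all(voxelData(renderCT(empty, defaultTissueTable())) == -1000))
    ## unknown label is named in the error
    badLab <- LabelVolume(array(c(0L, 99L), c(1, 2, 1)))
    expect_error(renderCT(badLab, defaultTissueTable()), "99")
})

test_that("CT and MRI renderings of one label map are co-registered", {
    lab <- makeLabels(PhantomSpec(gridDim = c(6L, 48L, 48L), seed = 3L))
    tt <- defaultTissueTable()
    ct <- renderCT(lab, tt)
    mri <- renderMRI(lab, tt)
    for (lv in unique(as.vector(voxelData(lab)))) {
        m <- voxelData(lab) == lv
        expect_equal(sd(voxelData(ct)[m]), 0)
        expect_equal(sd(voxelData(mri)[m]), 0)
    }
    ## single-label water organ: binary-valued {-1000, 0}
    one <- LabelVolume(array(c(0L, 1L), c(1, 2, 1)))
    water <- TissueTable(data.frame(label = 1L, name = "water",
                                    mu_120kev = 0.1615,
                                    mri_intensity = 100))
    expect_equal(sort(unique(as.vector(voxelData(renderCT(one, water))))),
                 c(-1000, 0))
})

test_that("an all-zero degradation spec is the identity", {
    lab <- makeLabels(PhantomSpec(gridDim = c(4L, 32L, 32L)))
    ct <- renderCT(lab, defaultTissueTable())
    out <- degradeVolume(ct, DegradationSpec(noiseSigma = 0, corrLen = 0,
                                             biasAmp = 0, textureAmp = 0))
    expect_equal(voxelData(out), voxelData(ct))
})

test_that("white-noise degradation recovers the requested sigma", {
    v <- ScanVolume(array(100, c(10, 40, 40)), modality = "CT")
    out <- degradeVolume(v, DegradationSpec(noiseSigma = 20, corrLen = 0,
                                            biasAmp = 0), seed = 9L)
    s <- sd(as.vector(voxelData(out) - voxelData(v)))
    expect_lt(abs(s - 20) / 20, 0.05)
})

test_that("degradation is seed-deterministic with stable mean", {
    v <- ScanVolume(array(100, c(10, 48, 48)), modality = "CT")
    spec <- DegradationSpec(noiseSigma = 10, corrLen = 0, biasAmp = 0)
    a <- degradeVolume(v, spec, seed = 1L)
    a2 <- degradeVolume(v, spec, seed = 1L)
    b <- degradeVolume(v, spec, seed = 2L)
    expect_identical(voxelData(a), voxelData(a2))
    expect_false(identical(voxelData(a), voxelData(b)))
    expect_lt(abs(mean(voxelData(a)) - mean(voxelData(b))) /
                  abs(mean(voxelData(v))), 0.01)
})

test_that("per-organ noise grows monotonically with noise sigma", {
    lab <- makeLabels(PhantomSpec(gridDim = c(6L, 48L, 48L)))
    ct <- renderCT(lab, defaultTissueTable())
    liver <- voxelData(lab) == 4L
    sds <- vapply(c(0, 5, 15, 30), function(s) {
        out <- degradeVolume(ct, DegradationSpec(noiseSigma = s,
                                                 corrLen = 0, biasAmp = 0),
                             seed = 4L)
        sd(voxelData(out)[liver])
    }, numeric(1))
    expect_true(all(diff(sds) > 0))
})
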