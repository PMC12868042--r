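test_that("adversarial loss has its closed-form values and monotonicity", {
    expect_equal(lossAdversarial(matrix(1, 4, 4)), 0)
    expect_equal(lossAdversarial(matrix(0.5, 4, 4)), log(2))
    expect_gt(lossAdversarial(matrix(0.1, 4, 4)),
              lossAdversarial(matrix(0.9, 4, 4)))
})

test_that("cycle and intensity losses are mean L1", {
    x <- matrix(rnorm(25), 5)
    expect_equal(lossCycle(x, x), 0)
    expect_equal(lossCycle(x, x + 0.3), 0.3)
    expect_equal(lossIntensity(x, x + 0.7), 0.7)
    a <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
    b <- matrix(c(1, 1, 0, 0), 2, byrow = TRUE)
    expect_equal(lossCycle(a, b), 0.5)
    ## brute-force oracle on a random pair
    set.seed(20)
    p <- matrix(rnorm(64), 8); q <- matrix(rnorm(64), 8)
    expect_equal(lossIntensity(p, q), oracleMAE(p, q), tolerance = 1e-12)
})

test_that("gradient-difference loss is shift-invariant with the 2x2 hand value", {
    set.seed(21)
    x <- matrix(rnorm(100), 10)
    expect_equal(lossGDL(x, x), 0)
    expect_equal(lossGDL(x, x + 3), 0)
    x2 <- matrix(c(0, 0, 0, 1), 2, byrow = TRUE)
    y2 <- matrix(0, 2, 2)
    expect_equal(lossGDL(x2, y2, reduce = "sum"), 2)
    expect_error(lossGDL(x, matrix(0, 3, 3)), "shape")
})

test_that("the generator total is the exact weighted recombination", {
    parts <- list(gan = 1, cycXY = 1, cycYX = 1, int = 1, gdl = 1)
    expect_equal(lossGeneratorTotal(parts, ganConfig(lambdaInt = 0.5,
                                                     lambdaGdl = 0.5)), 22)
    expect_equal(lossGeneratorTotal(parts, ganConfigCT()), 23)
    zero <- list(gan = 0, cycXY = 0, cycYX = 0, int = 0, gdl = 0)
    expect_equal(lossGeneratorTotal(zero, ganConfigCT()), 0)
    ## random decomposition identity
    set.seed(22)
    p <- list(gan = runif(1), cycXY = runif(1), cycYX = runif(1),
              int = runif(1), gdl = runif(1))
    cfg <- ganConfig(lambdaInt = 2, lambdaGdl = 0.3)
    expect_equal(lossGeneratorTotal(p, cfg),
                 p$gan + 10 * (p$cycXY + p$cycYX) + 2 * p$int + 0.3 * p$gdl,
                 tolerance = 1e-12)
})

test_that("discriminator loss halves the BCE pair", {
    expect_equal(lossDiscriminator(matrix(1, 3, 3), matrix(1e-9, 3, 3)), 0,
                 tolerance = 1e-5)
    expect_equal(lossDiscriminator(matrix(0.5, 3, 3), matrix(0.5, 3, 3)),
                 log(2))
    set.seed(23)
    dr <- matrix(runif(16, 0.1, 0.9), 4)
    df <- matrix(runif(16, 0.1, 0.9), 4)
    unhalved <- mean(-log(dr)) + mean(-log(1 - df))
    expect_equal(lossDiscriminator(dr, df), unhalved / 2, tolerance = 1e-12)
})

test_that("the image buffer obeys capacity and the one-half return rule", {
    set.seed(24)
    b <- newImageBuffer(1L)
    first <- matrix(1, 2, 2)
    expect_identical(bufferPush(b, first), first)
    b2 <- newImageBuffer(5L)
    for (i in 1:50) bufferPush(b2, matrix(i, 1, 1))
    expect_lte(length(b2$items), 5L)
    ## Monte-Carlo of the 1/2 historical-return rule
    b3 <- newImageBuffer(10L)
    for (i in 1:10) bufferPush(b3, i)
    n <- 10000L
    hist <- 0L
    for (i in seq_len(n)) {
        out <- bufferPush(b3, 1e6 + i)
        if (out != 1e6 + i) hist <- hist + 1L
    }
    expect_lt(abs(hist / n - 0.5), 0.02)
})
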