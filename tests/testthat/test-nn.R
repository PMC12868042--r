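pf <- asNamespace("phantomForge")

test_that("generator preserves spatial size and stays inside tanh range", {
    set.seed(10)
    cfg <- ganConfig(baseFilters = 8L, nResBlocks = 1L, inputSize = 64L)
    G <- buildGenerator(cfg)
    for (side in c(64L, 96L)) {
        x <- array(rnorm(side * side), c(side, side, 1))
        y <- pf$.netForward(G$layers, x, train = FALSE)$y
        expect_identical(dim(y), c(side, side, 1L))
        expect_true(all(y > -1 & y < 1))
    }
    expect_error(buildGenerator(ganConfig(inputSize = 66L)), "divisible")
})

test_that("discriminator outputs a sigmoid map with the PatchGAN geometry", {
    set.seed(11)
    cfg <- ganConfig(baseFilters = 8L, nResBlocks = 1L, inputSize = 256L)
    D <- buildDiscriminator(cfg)
    x <- array(rnorm(256 * 256), c(256, 256, 1))
    y <- pf$.netForward(D$layers, x, train = FALSE)$y
    expect_identical(dim(y)[1:2], c(30L, 30L))
    expect_true(all(y > 0 & y < 1))
    expect_error(buildDiscriminator(ganConfig(inputSize = 8L)), "at least")
})

test_that("backpropagated gradients match central finite differences", {
    set.seed(12)
    net <- list(pf$.layerConv(1L, 2L, 3L, 2L, 1L, "reflect"),
                pf$.layerINorm(2L), pf$.layerRelu(),
                pf$.layerResBlock(2L),
                pf$.layerUpsample(),
                pf$.layerConv(2L, 1L, 3L, 1L, 1L, "zero"),
                pf$.layerTanh())
    xs <- array(rnorm(8 * 8), c(8, 8, 1))
    lossOf <- function(net, xs)
        sum(pf$.netForward(net, xs, train = FALSE)$y^2)
    fw <- pf$.netForward(net, xs, train = TRUE)
    bk <- pf$.netBackward(net, fw$caches, 2 * fw$y)
    eps <- 1e-6
    relErr <- function(nu, an) max(abs(nu - an) / (abs(nu) + 1e-6))
    idxs <- sample(length(xs), 8)
    nu <- vapply(idxs, function(i) {
        xp <- xs; xp[i] <- xp[i] + eps
        xm <- xs; xm[i] <- xm[i] - eps
        (lossOf(net, xp) - lossOf(net, xm)) / (2 * eps)
    }, numeric(1))
    expect_lt(relErr(nu, bk$dx[idxs]), 1e-4)
    idw <- sample(length(net[[1]]$W), 6)
    nuW <- vapply(idw, function(i) {
        n2 <- net; n2[[1]]$W[i] <- n2[[1]]$W[i] + eps
        n3 <- net; n3[[1]]$W[i] <- n3[[1]]$W[i] - eps
        (lossOf(n2, xs) - lossOf(n3, xs)) / (2 * eps)
    }, numeric(1))
    expect_lt(relErr(nuW, bk$grads[[1]]$W[idw]), 1e-4)
    ## residual-block sub-layer parameters
    idr <- sample(length(net[[4]]$layers[[1]]$W), 4)
    nuR <- vapply(idr, function(i) {
        n2 <- net; n2[[4]]$layers[[1]]$W[i] <- n2[[4]]$layers[[1]]$W[i] + eps
        n3 <- net; n3[[4]]$layers[[1]]$W[i] <- n3[[4]]$layers[[1]]$W[i] - eps
        (lossOf(n2, xs) - lossOf(n3, xs)) / (2 * eps)
    }, numeric(1))
    expect_lt(relErr(nuR, bk$grads[[4]][[1]]$W[idr]), 1e-4)
    ## instance-norm affine parameters
    nuG <- vapply(seq_along(net[[2]]$gamma), function(i) {
        n2 <- net; n2[[2]]$gamma[i] <- n2[[2]]$gamma[i] + eps
        n3 <- net; n3[[2]]$gamma[i] <- n3[[2]]$gamma[i] - eps
        (lossOf(n2, xs) - lossOf(n3, xs)) / (2 * eps)
    }, numeric(1))
    expect_lt(relErr(nuG, bk$grads[[2]]$gamma), 1e-4)
})

test_that("bilinear upsampling and its adjoint form a transpose pair", {
    set.seed(13)
    x <- array(rnorm(6 * 5), c(6, 5, 1))
    y <- array(rnorm(12 * 10), c(12, 10, 1))
    lhs <- sum(pf$.upsample2x(x) * y)
    rhs <- sum(x * pf$.upsample2xGrad(y, c(6L, 5L)))
    expect_equal(lhs, rhs, tolerance = 1e-10)
})
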