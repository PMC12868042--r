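#' GanConfig: CycleGAN hyper-parameters
#'
#' Defaults follow the standard unpaired-translation recipe: cycle weight
#' 10, adversarial weight 1, generator learning rate 2e-4, batch size 1,
#' image buffer of 50, nine residual blocks on 256 x 256 inputs. The
#' intensity and gradient-difference weights and the discriminator
#' learning rate are the tunable additions; see [ganConfigCT()] /
#' [ganConfigMRI()] for the selected working points of the two modalities.
#'
#' @slot lambdaCyc cycle-consistency weight (default 10).
#' @slot lambdaAdv adversarial weight (default 1).
#' @slot lambdaInt intensity-loss weight.
#' @slot lambdaGdl gradient-difference-loss weight.
#' @slot lrG generator learning rate (default 2e-4).
#' @slot lrD discriminator learning rate.
#' @slot epochs training epochs.
#' @slot batchSize batch size (1).
#' @slot bufferK discriminator image-buffer capacity (50).
#' @slot nResBlocks residual blocks in the generators (9 at full scale).
#' @slot baseFilters stem width of generators/discriminators (64 at full
#'   scale).
#' @slot inputSize network input side in pixels (256 at full scale; must
#'   be divisible by 4).
#' @slot seed integer seed fixing initialization and sampling.
#' @exportClass GanConfig
setClass("GanConfig",
    representation(lambdaCyc = "numeric", lambdaAdv = "numeric",
                   lambdaInt = "numeric", lambdaGdl = "numeric",
                   lrG = "numeric", lrD = "numeric", epochs = "integer",
                   batchSize = "integer", bufferK = "integer",
                   nResBlocks = "integer", baseFilters = "integer",
                   inputSize = "integer", seed = "integer"),
    prototype(lambdaCyc = 10, lambdaAdv = 1, lambdaInt = 0, lambdaGdl = 0,
              lrG = 2e-4, lrD = 2e-5, epochs = 150L, batchSize = 1L,
              bufferK = 50L, nResBlocks = 9L, baseFilters = 64L,
              inputSize = 256L, seed = 1L)
)

setValidity("GanConfig", function(object) {
    msg <- character()
    if (any(c(object@lambdaCyc, object@lambdaAdv, object@lambdaInt,
              object@lambdaGdl) < 0))
        msg <- c(msg, "all loss weights must be >= 0")
    if (object@lrG <= 0 || object@lrD <= 0)
        msg <- c(msg, "learning rates must be positive")
    if (object@bufferK < 1L) msg <- c(msg, "bufferK must be >= 1")
    if (object@nResBlocks < 1L) msg <- c(msg, "nResBlocks must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a GanConfig
#' @param lambdaCyc,lambdaAdv,lambdaInt,lambdaGdl loss weights.
#' @param lrG,lrD generator / discriminator learning rates.
#' @param epochs,batchSize,bufferK training schedule parameters.
#' @param nResBlocks,baseFilters,inputSize architecture size.
#' @param seed integer seed.
#' @return A \linkS4class{GanConfig}.
#' @export
ganConfig <- function(lambdaCyc = 10, lambdaAdv = 1, lambdaInt = 0,
                      lambdaGdl = 0, lrG = 2e-4, lrD = 2e-5, epochs = 150L,
                      batchSize = 1L, bufferK = 50L, nResBlocks = 9L,
                      baseFilters = 64L, inputSize = 256L, seed = 1L) {
    new("GanConfig", lambdaCyc = lambdaCyc, lambdaAdv = lambdaAdv,
        lambdaInt = lambdaInt, lambdaGdl = lambdaGdl, lrG = lrG, lrD = lrD,
        epochs = as.integer(epochs), batchSize = as.integer(batchSize),
        bufferK = as.integer(bufferK), nResBlocks = as.integer(nResBlocks),
        baseFilters = as.integer(baseFilters),
        inputSize = as.integer(inputSize), seed = as.integer(seed))
}

#' Selected full-scale working points for the two modalities
#'
#' The CT network uses intensity and gradient-difference weights of 1 with
#' a discriminator learning rate of 2e-5 (a faster discriminator was found
#' to overpower the generator on CT); the MRI network uses weights of 0.5
#' with a discriminator learning rate of 2e-4.
#'
#' @param ... overrides passed to [ganConfig()].
#' @return A \linkS4class{GanConfig}.
#' @export
ganConfigCT <- function(...)
    ganConfig(lambdaInt = 1, lambdaGdl = 1, lrD = 2e-5, ...)

#' @rdname ganConfigCT
#' @export
ganConfigMRI <- function(...)
    ganConfig(lambdaInt = 0.5, lambdaGdl = 0.5, lrD = 2e-4, ...)

## ---- Architectures ----------------------------------------------------

#' Build the ResNet-style generator
#'
#' Three encoding blocks (7x7 stem then two stride-2 downsamplers),
#' \code{nResBlocks} residual blocks, and two bilinear-upsample + conv
#' decoding blocks, with reflection padding and instance normalization
#' throughout and a tanh output head. The output has the spatial size of
#' the input for any input divisible by 4.
#'
#' @param cfg a \linkS4class{GanConfig}.
#' @return A generator network object.
#' @export
buildGenerator <- function(cfg) {
    if (cfg@inputSize %% 4L != 0L)
        stop("generator input size must be divisible by 4, got ",
             cfg@inputSize)
    b <- cfg@baseFilters
    layers <- c(
        list(.layerConv(1L, b, 7L, 1L, 3L, "reflect"),
             .layerINorm(b), .layerRelu(),
             .layerConv(b, 2L * b, 3L, 2L, 1L, "reflect"),
             .layerINorm(2L * b), .layerRelu(),
             .layerConv(2L * b, 4L * b, 3L, 2L, 1L, "reflect"),
             .layerINorm(4L * b), .layerRelu()),
        lapply(seq_len(cfg@nResBlocks), function(i) .layerResBlock(4L * b)),
        list(.layerUpsample(),
             .layerConv(4L * b, 2L * b, 3L, 1L, 1L, "reflect"),
             .layerINorm(2L * b), .layerRelu(),
             .layerUpsample(),
             .layerConv(2L * b, b, 3L, 1L, 1L, "reflect"),
             .layerINorm(b), .layerRelu(),
             .layerConv(b, 1L, 7L, 1L, 3L, "reflect"),
             .layerTanh())
    )
    structure(list(layers = layers, kind = "generator"), class = "pfNet")
}

#' Build the 70 x 70 patch-classifying discriminator
#'
#' Five 4x4 convolution layers with strides 2, 2, 2, 1, 1 and padding 1
#' (instance normalization on the middle layers) and a sigmoid map head:
#' each output unit scores a 70 x 70 receptive field as real (1) or fake
#' (0); a 256 x 256 input yields a 30 x 30 map.
#'
#' @param cfg a \linkS4class{GanConfig}.
#' @return A discriminator network object.
#' @export
buildDiscriminator <- function(cfg) {
    ## Inputs of at least 16 px survive the five-conv stack (a 70 px input
    ## fills one full receptive field); smaller inputs cannot be scored.
    if (cfg@inputSize < 16L)
        stop("discriminator input must be at least 16 pixels, got ",
             cfg@inputSize)
    b <- cfg@baseFilters
    layers <- list(
        .layerConv(1L, b, 4L, 2L, 1L, "zero"), .layerLRelu(),
        .layerConv(b, 2L * b, 4L, 2L, 1L, "zero"),
        .layerINorm(2L * b), .layerLRelu(),
        .layerConv(2L * b, 4L * b, 4L, 2L, 1L, "zero"),
        .layerINorm(4L * b), .layerLRelu(),
        .layerConv(4L * b, 8L * b, 4L, 1L, 1L, "zero"),
        .layerINorm(8L * b), .layerLRelu(),
        .layerConv(8L * b, 1L, 4L, 1L, 1L, "zero"), .layerSigmoid()
    )
    structure(list(layers = layers, kind = "discriminator"), class = "pfNet")
}

#' Identity generator (plumbing test hook)
#'
#' A generator stand-in whose forward pass returns its input unchanged;
#' useful for verifying the tile / resize / fuse plumbing around
#' [predictVolume()].
#'
#' @return An identity network object.
#' @export
identityGenerator <- function()
    structure(list(layers = list(), kind = "identity"), class = "pfNet")

.netApply <- function(net, x, train = FALSE) {
    if (net$kind == "identity") return(list(y = x, caches = NULL))
    .netForward(net$layers, x, train = train)
}

#' Receptive field of one discriminator output unit
#'
#' Computed by the standard receptive-field recursion over the network's
#' actual convolution layers: rf <- rf + (k - 1) * jump; jump <- jump *
#' stride.
#'
#' @param disc a discriminator from [buildDiscriminator()].
#' @return Receptive field side length in input pixels.
#' @export
discriminatorReceptiveField <- function(disc) {
    rf <- 1L; jump <- 1L
    for (l in disc$layers) {
        if (l$type != "conv") next
        rf <- rf + (l$k - 1L) * jump
        jump <- jump * l$stride
    }
    rf
}

## ---- Losses -----------------------------------------------------------

.logEps <- 1e-7

#' Adversarial loss of a discriminator output map
#'
#' Binary cross-entropy against the "real" target: the mean of
#' \code{-log(dOut)} over the map (epsilon-clamped). Zero when the
#' discriminator scores every unit as real, \code{log(2)} at the
#' uninformative 0.5 output.
#'
#' @param dOut discriminator output map with values in (0, 1).
#' @return Non-negative scalar.
#' @export
lossAdversarial <- function(dOut) mean(-log(pmax(dOut, .logEps)))

#' Cycle-consistency loss (mean L1)
#'
#' Mean absolute difference between an image and its cycle-reconstructed
#' version; the full cycle term sums the forward and backward directions.
#'
#' @param x original patch.
#' @param xCycled cycled reconstruction (same shape).
#' @return Non-negative scalar.
#' @export
lossCycle <- function(x, xCycled) mean(abs(x - xCycled))

#' Intensity loss (mean L1 between input and its translation)
#'
#' Anchors organ intensities: penalizes the mean absolute difference
#' between the input phantom patch and the generated translation.
#'
#' @param x input patch.
#' @param gx generated translation of \code{x}.
#' @return Non-negative scalar.
#' @export
lossIntensity <- function(x, gx) mean(abs(gx - x))

#' Gradient-difference loss
#'
#' Penalizes discrepancies between the absolute first-order image
#' gradients of \code{x} and \code{y} along rows and columns:
#' the mean over valid positions of
#' \code{(|dv x| - |dv y|)^2 + (|dh x| - |dh y|)^2} with forward
#' differences \code{dv X = X[i,j] - X[i-1,j]},
#' \code{dh X = X[i,j] - X[i,j-1]}. Invariant to constant offsets.
#'
#' @param x,y numeric matrices of identical shape.
#' @param reduce \code{"mean"} (default) or \code{"sum"}.
#' @return Non-negative scalar.
#' @export
lossGDL <- function(x, y, reduce = c("mean", "sum")) {
    reduce <- match.arg(reduce)
    if (!all(dim(x) == dim(y))) stop("shape mismatch in gradient loss")
    h <- nrow(x); w <- ncol(x)
    dvx <- abs(x[-1, , drop = FALSE] - x[-h, , drop = FALSE])
    dvy <- abs(y[-1, , drop = FALSE] - y[-h, , drop = FALSE])
    dhx <- abs(x[, -1, drop = FALSE] - x[, -w, drop = FALSE])
    dhy <- abs(y[, -1, drop = FALSE] - y[, -w, drop = FALSE])
    s <- sum((dvx - dvy)^2) + sum((dhx - dhy)^2)
    if (reduce == "sum") s else s / ((h - 1) * w + h * (w - 1))
}

## Gradient of lossGDL (mean reduction) with respect to y.
.lossGDLGradY <- function(x, y) {
    h <- nrow(x); w <- ncol(x)
    n <- (h - 1) * w + h * (w - 1)
    dvy <- y[-1, , drop = FALSE] - y[-h, , drop = FALSE]
    dvx <- x[-1, , drop = FALSE] - x[-h, , drop = FALSE]
    dhy <- y[, -1, drop = FALSE] - y[, -w, drop = FALSE]
    dhx <- x[, -1, drop = FALSE] - x[, -w, drop = FALSE]
    tv <- 2 * (abs(dvy) - abs(dvx)) * sign(dvy) / n
    th <- 2 * (abs(dhy) - abs(dhx)) * sign(dhy) / n
    g <- matrix(0, h, w)
    g[-1, ] <- g[-1, , drop = FALSE] + tv
    g[-h, ] <- g[-h, , drop = FALSE] - tv
    g[, -1] <- g[, -1, drop = FALSE] + th
    g[, -w] <- g[, -w, drop = FALSE] - th
    g
}

#' Total generator objective
#'
#' Weighted recombination of the generator loss components for one
#' direction: adversarial + lambdaCyc * (both cycle terms) + lambdaInt *
#' intensity + lambdaGdl * gradient difference.
#'
#' @param parts named list with elements \code{gan}, \code{cycXY},
#'   \code{cycYX}, \code{int}, \code{gdl}.
#' @param cfg a \linkS4class{GanConfig} supplying the weights.
#' @return Scalar total loss.
#' @export
lossGeneratorTotal <- function(parts, cfg) {
    cfg@lambdaAdv * parts$gan +
        cfg@lambdaCyc * (parts$cycXY + parts$cycYX) +
        cfg@lambdaInt * parts$int +
        cfg@lambdaGdl * parts$gdl
}

#' Discriminator loss (halved BCE pair)
#'
#' \code{0.5 * [BCE(1, dReal) + BCE(0, dFake)]}: half the sum of the
#' binary cross-entropies on a real map (target 1) and a generated map
#' (target 0). The fixed factor of 2 slows the discriminator relative to
#' the generator. Equals \code{log(2)} when both maps sit at the
#' uninformative 0.5.
#'
#' @param dReal,dFake discriminator output maps in (0, 1).
#' @return Non-negative scalar.
#' @export
lossDiscriminator <- function(dReal, dFake)
    0.5 * (mean(-log(pmax(dReal, .logEps))) +
           mean(-log(pmax(1 - dFake, .logEps))))

## ---- Image buffer -----------------------------------------------------

#' Create / push to a generated-image history buffer
#'
#' The discriminators are trained on a randomly selected image from a
#' buffer of the last K generated images rather than always on the newest
#' one. While the buffer is filling, the pushed image is stored and
#' returned; once full, with probability 1/2 a uniformly chosen stored
#' image is returned (and replaced by the new one), otherwise the new
#' image is returned. Draws come from the active RNG stream, so a seeded
#' training run is reproducible.
#'
#' @param K buffer capacity (>= 1).
#' @return \code{newImageBuffer}: an opaque buffer object.
#' @export
newImageBuffer <- function(K) {
    env <- new.env(parent = emptyenv())
    env$K <- as.integer(K)
    env$items <- vector("list", 0L)
    class(env) <- "pfImageBuffer"
    env
}

#' @rdname newImageBuffer
#' @param buffer a buffer from [newImageBuffer()].
#' @param img image (any array) to push.
#' @return \code{bufferPush}: the image to train the discriminator on.
#' @export
bufferPush <- function(buffer, img) {
    n <- length(buffer$items)
    if (n < buffer$K) {
        buffer$items[[n + 1L]] <- img
        return(img)
    }
    if (stats::runif(1) < 0.5) {
        i <- sample.int(buffer$K, 1L)
        out <- buffer$items[[i]]
        buffer$items[[i]] <- img
        out
    } else {
        img
    }
}

## ---- Bundle & training ------------------------------------------------

#' GanBundle: the trained two-generator / two-discriminator model
#'
#' @slot G phantom-to-patient generator.
#' @slot F patient-to-phantom generator.
#' @slot DX,DY domain discriminators.
#' @slot config the \linkS4class{GanConfig} used.
#' @slot history per-epoch mean loss components (data.frame).
#' @exportClass GanBundle
setOldClass("pfNet")

setClass("GanBundle",
    representation(G = "ANY", F = "ANY", DX = "ANY", DY = "ANY",
                   config = "GanConfig", history = "data.frame"))

setMethod("show", "GanBundle", function(object) {
    cat(sprintf(
        "GanBundle: %d res blocks, base %d, input %d; trained %d epochs\n",
        object@config@nResBlocks, object@config@baseFilters,
        object@config@inputSize, nrow(object@history)))
})

.asPatchArray <- function(p) {
    if (is.matrix(p)) array(p, c(dim(p), 1L)) else p
}

.checkFinite <- function(value, component) {
    if (!is.finite(value))
        stop("non-finite ", component,
             " loss encountered; training aborted", call. = FALSE)
    value
}

#' Train a CycleGAN on two unpaired patch domains
#'
#' Per iteration (batch size 1): both generators are updated on their
#' full composite objectives (adversarial + weighted cycle terms +
#' intensity + gradient difference; the shared cycle terms send gradients
#' to both generators), then each discriminator is updated on the halved
#' BCE pair using a buffered generated image. Adam (beta1 = 0.5) with
#' constant learning rates. Fully reproducible per config seed.
#'
#' @param domainX list of phantom-domain patches (square matrices in
#'   [-1, 1], side = \code{cfg@inputSize}).
#' @param domainY list of patient-domain patches, same geometry.
#' @param cfg a \linkS4class{GanConfig}.
#' @param checkpointDir optional directory receiving per-epoch generator
#'   checkpoints (\code{epoch_<n>.rds}).
#' @param verbose print per-epoch summaries.
#' @return A \linkS4class{GanBundle} with per-epoch loss history.
#' @export
trainCycleGAN <- function(domainX, domainY, cfg, checkpointDir = NULL,
                          verbose = FALSE) {
    if (!length(domainX) || !length(domainY))
        stop("both patch domains must be non-empty")
    domainX <- lapply(domainX, .asPatchArray)
    domainY <- lapply(domainY, .asPatchArray)
    .withSeed(cfg@seed, {
        G <- buildGenerator(cfg)
        FF <- buildGenerator(cfg)
        DX <- buildDiscriminator(cfg)
        DY <- buildDiscriminator(cfg)
        optG <- .netAdamInit(G$layers); optF <- .netAdamInit(FF$layers)
        optDX <- .netAdamInit(DX$layers); optDY <- .netAdamInit(DY$layers)
        bufX <- newImageBuffer(cfg@bufferK)
        bufY <- newImageBuffer(cfg@bufferK)
        nIter <- max(length(domainX), length(domainY))
        hist <- vector("list", cfg@epochs)
        t <- 0L
        for (epoch in seq_len(cfg@epochs)) {
            ordX <- sample(rep_len(seq_along(domainX), nIter))
            ordY <- sample(rep_len(seq_along(domainY), nIter))
            acc <- NULL
            for (it in seq_len(nIter)) {
                t <- t + 1L
                step <- .cycleGanStep(domainX[[ordX[it]]],
                                      domainY[[ordY[it]]],
                                      G, FF, DX, DY, cfg, bufX, bufY)
                res <- .netAdamStep(G$layers, step$gradG, optG, cfg@lrG, t)
                G$layers <- res$layers; optG <- res$state
                res <- .netAdamStep(FF$layers, step$gradF, optF, cfg@lrG, t)
                FF$layers <- res$layers; optF <- res$state
                res <- .netAdamStep(DX$layers, step$gradDX, optDX, cfg@lrD, t)
                DX$layers <- res$layers; optDX <- res$state
                res <- .netAdamStep(DY$layers, step$gradDY, optDY, cfg@lrD, t)
                DY$layers <- res$layers; optDY <- res$state
                acc <- rbind(acc, unlist(step$losses))
            }
            em <- colMeans(acc)
            hist[[epoch]] <- c(epoch = epoch, em)
            if (verbose)
                message(sprintf("epoch %d: G %.4f / D %.4f / cyc %.4f",
                                epoch, em[["totalG_XY"]], em[["lossDY"]],
                                em[["cycXY"]] + em[["cycYX"]]))
            if (!is.null(checkpointDir)) {
                dir.create(checkpointDir, showWarnings = FALSE,
                           recursive = TRUE)
                saveRDS(list(G = G, F = FF, epoch = epoch, config = cfg),
                        file.path(checkpointDir,
                                  sprintf("epoch_%03d.rds", epoch)))
            }
        }
        history <- if (cfg@epochs > 0)
            as.data.frame(do.call(rbind, hist))
        else data.frame()
        new("GanBundle", G = G, F = FF, DX = DX, DY = DY, config = cfg,
            history = history)
    })
}

## One optimization step: returns generator/discriminator gradients and
## the loss breakdown. Both directions share one forward pass.
.cycleGanStep <- function(x, y, G, FF, DX, DY, cfg, bufX, bufY) {
    n <- length(x)
    fGx <- .netForward(G$layers, x, train = TRUE);  fakeY <- fGx$y
    fFy <- .netForward(FF$layers, y, train = TRUE); fakeX <- fFy$y
    fFfy <- .netForward(FF$layers, fakeY, train = TRUE); recX <- fFfy$y
    fGfx <- .netForward(G$layers, fakeX, train = TRUE);  recY <- fGfx$y
    dYfy <- .netForward(DY$layers, fakeY, train = TRUE)
    dXfx <- .netForward(DX$layers, fakeX, train = TRUE)

    xm <- array(x, dim(x)[1:2]); ym <- array(y, dim(y)[1:2])
    fym <- array(fakeY, dim(x)[1:2]); fxm <- array(fakeX, dim(y)[1:2])
    losses <- list(
        ganXY = .checkFinite(lossAdversarial(dYfy$y), "adversarial XY"),
        ganYX = .checkFinite(lossAdversarial(dXfx$y), "adversarial YX"),
        cycXY = .checkFinite(lossCycle(x, recX), "cycle XY"),
        cycYX = .checkFinite(lossCycle(y, recY), "cycle YX"),
        intXY = .checkFinite(lossIntensity(x, fakeY), "intensity XY"),
        intYX = .checkFinite(lossIntensity(y, fakeX), "intensity YX"),
        gdlXY = .checkFinite(lossGDL(xm, fym), "gradient-difference XY"),
        gdlYX = .checkFinite(lossGDL(ym, fxm), "gradient-difference YX")
    )
    losses$totalG_XY <- lossGeneratorTotal(
        list(gan = losses$ganXY, cycXY = losses$cycXY, cycYX = losses$cycYX,
             int = losses$intXY, gdl = losses$gdlXY), cfg)
    losses$totalG_YX <- lossGeneratorTotal(
        list(gan = losses$ganYX, cycXY = losses$cycXY, cycYX = losses$cycYX,
             int = losses$intYX, gdl = losses$gdlYX), cfg)

    ## generator gradients ------------------------------------------------
    dRecX <- cfg@lambdaCyc * sign(recX - x) / n
    dRecY <- cfg@lambdaCyc * sign(recY - y) / n
    bF1 <- .netBackward(FF$layers, fFfy$caches, dRecX)    # -> d fakeY
    bG1 <- .netBackward(G$layers, fGfx$caches, dRecY)     # -> d fakeX

    nMapY <- length(dYfy$y); nMapX <- length(dXfx$y)
    dAdvY <- array(-cfg@lambdaAdv / pmax(dYfy$y, .logEps) / nMapY,
                   dim(dYfy$y))
    dAdvX <- array(-cfg@lambdaAdv / pmax(dXfx$y, .logEps) / nMapX,
                   dim(dXfx$y))
    bDY <- .netBackward(DY$layers, dYfy$caches, dAdvY)    # data grad only
    bDX <- .netBackward(DX$layers, dXfx$caches, dAdvX)

    dFakeY <- bF1$dx + bDY$dx +
        cfg@lambdaInt * sign(fakeY - x) / n +
        cfg@lambdaGdl * array(.lossGDLGradY(xm, fym), dim(x))
    dFakeX <- bG1$dx + bDX$dx +
        cfg@lambdaInt * sign(fakeX - y) / n +
        cfg@lambdaGdl * array(.lossGDLGradY(ym, fxm), dim(y))

    bG2 <- .netBackward(G$layers, fGx$caches, dFakeY)
    bF2 <- .netBackward(FF$layers, fFy$caches, dFakeX)
    gradG <- .netAccumulate(bG1$grads, bG2$grads)
    gradF <- .netAccumulate(bF1$grads, bF2$grads)

    ## discriminator gradients (on buffered fakes) ------------------------
    fakeYb <- bufferPush(bufY, fakeY)
    fakeXb <- bufferPush(bufX, fakeX)
    gradDY <- .discGrads(DY, y, fakeYb)
    gradDX <- .discGrads(DX, x, fakeXb)
    losses$lossDY <- .checkFinite(gradDY$loss, "discriminator Y")
    losses$lossDX <- .checkFinite(gradDX$loss, "discriminator X")

    list(gradG = gradG, gradF = gradF,
         gradDX = gradDX$grads, gradDY = gradDY$grads, losses = losses)
}

.discGrads <- function(D, real, fake) {
    fr <- .netForward(D$layers, real, train = TRUE)
    ff <- .netForward(D$layers, fake, train = TRUE)
    loss <- lossDiscriminator(fr$y, ff$y)
    nR <- length(fr$y); nF <- length(ff$y)
    dReal <- array(-0.5 / pmax(fr$y, .logEps) / nR, dim(fr$y))
    dFake <- array(0.5 / pmax(1 - ff$y, .logEps) / nF, dim(ff$y))
    g <- .netAccumulate(.netBackward(D$layers, fr$caches, dReal)$grads,
                        .netBackward(D$layers, ff$caches, dFake)$grads)
    list(grads = g, loss = loss)
}

## ---- Volume inference -------------------------------------------------

#' Translate a whole normalized volume through a trained generator
#'
#' Per axial slice: deterministic tiling, bilinear resize of each patch to
#' the network input size, generator forward pass, resize back to the
#' native patch size, denormalization to the physical range, and mean
#' patch fusion. The output carries the source geometry.
#'
#' @param bundle a \linkS4class{GanBundle}, or a generator network (e.g.
#'   [identityGenerator()]).
#' @param vol normalized \linkS4class{ScanVolume} (values in [-1, 1]) with
#'   a recorded intensity range.
#' @param patchSize native tiling patch side (default 220).
#' @param stride tiling stride (default 64).
#' @param direction \code{"XY"} (phantom to patient, default) or
#'   \code{"YX"}.
#' @return Denormalized \linkS4class{ScanVolume} in physical units.
#' @export
predictVolume <- function(bundle, vol, patchSize = 220L, stride = 64L,
                          direction = c("XY", "YX")) {
    direction <- match.arg(direction)
    gen <- if (is(bundle, "GanBundle")) {
        if (direction == "XY") bundle@G else bundle@F
    } else bundle
    inputSize <- if (is(bundle, "GanBundle")) bundle@config@inputSize
                 else NULL
    ir <- intensityRange(vol)
    if (any(!is.finite(ir)))
        stop("predictVolume needs a volume with a recorded intensity range")
    arr <- voxelData(vol)
    d <- dim(arr)
    out <- array(0, d)
    for (k in seq_len(d[1])) {
        sl <- array(arr[k, , ], dim = d[2:3])
        grid <- tileForInference(sl, patchSize, stride)
        preds <- lapply(patchData(grid), function(p) {
            q <- if (is.null(inputSize)) p else resizePatch(p, inputSize)
            o <- .netApply(gen, array(q, c(dim(q), 1L)))$y
            o <- array(o, dim(o)[1:2])
            o <- resizePatch(o, patchSize)
            o[o < -1] <- -1; o[o > 1] <- 1
            (o + 1) / 2 * (ir[2] - ir[1]) + ir[1]
        })
        out[k, , ] <- fuseMean(grid, preds)
    }
    ScanVolume(out, spacing = voxelSpacing(vol), modality = modality(vol),
               intensityRange = ir)
}
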