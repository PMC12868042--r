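## Layer objects are plain lists with a `type` field; a network is a list
## of layers. Parameters are initialized from the current RNG stream
## (weights ~ N(0, 0.02), biases 0), so seeding the stream fixes the
## model. Residual blocks hold their own sub-layer list.

.layerConv <- function(cin, cout, k, stride = 1L, pad = 0L,
                       padMode = c("zero", "reflect")) {
    padMode <- match.arg(padMode)
    W <- array(stats::rnorm(k * k * cin * cout, sd = 0.02),
               c(k, k, cin, cout))
    list(type = "conv", k = as.integer(k), stride = as.integer(stride),
         pad = as.integer(pad), padMode = padMode,
         W = W, b = numeric(cout))
}

.layerINorm <- function(c) list(type = "inorm", gamma = rep(1, c),
                                beta = numeric(c))
.layerRelu <- function() list(type = "relu")
.layerLRelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
.layerTanh <- function() list(type = "tanh")
.layerSigmoid <- function() list(type = "sigmoid")
.layerUpsample <- function() list(type = "upsample2x")
.layerResBlock <- function(c, k = 3L) {
    list(type = "resblock", layers = list(
        .layerConv(c, c, k, 1L, 1L, "reflect"),
        .layerINorm(c),
        .layerRelu(),
        .layerConv(c, c, k, 1L, 1L, "reflect"),
        .layerINorm(c)
    ))
}

.layerForward <- function(layer, x, train = TRUE) {
    switch(layer$type,
        conv = {
            xp <- if (layer$padMode == "reflect")
                .padReflect(x, layer$pad) else .padZero(x, layer$pad)
            Wmat <- matrix(layer$W, layer$k * layer$k * dim(layer$W)[3],
                           dim(layer$W)[4])
            res <- .convForwardRaw(xp, Wmat, layer$b, layer$k, layer$k,
                                   layer$stride, keep = train)
            list(y = res$y,
                 cache = if (train) list(Xcol = res$Xcol, xpDim = dim(xp)))
        },
        inorm = {
            res <- .instNormForward(x, layer$gamma, layer$beta)
            list(y = res$y, cache = if (train) res[c("xhat", "invstd")])
        },
        relu = list(y = pmax(x, 0), cache = if (train) list(pos = x > 0)),
        lrelu = {
            y <- ifelse(x > 0, x, layer$slope * x)
            dim(y) <- dim(x)
            list(y = y, cache = if (train) list(pos = x > 0))
        },
        tanh = {
            y <- tanh(x)
            list(y = y, cache = if (train) list(y = y))
        },
        sigmoid = {
            y <- 1 / (1 + exp(-x))
            list(y = y, cache = if (train) list(y = y))
        },
        upsample2x = list(y = .upsample2x(x),
                          cache = if (train) list(hw = dim(x)[1:2])),
        resblock = {
            res <- .netForward(layer$layers, x, train = train)
            list(y = x + res$y, cache = if (train) res$caches)
        },
        stop("unknown layer type ", layer$type)
    )
}

.layerBackward <- function(layer, cache, dy) {
    switch(layer$type,
        conv = {
            res <- .convBackwardRaw(dy, cache$Xcol, layer$W, cache$xpDim,
                                    layer$stride)
            dx <- if (layer$padMode == "reflect")
                .unpadReflectGrad(res$dx, layer$pad)
            else .unpadZeroGrad(res$dx, layer$pad)
            list(dx = dx, grads = list(W = res$dW, b = res$db))
        },
        inorm = {
            res <- .instNormBackward(dy, cache, layer$gamma)
            list(dx = res$dx, grads = list(gamma = res$dg, beta = res$db))
        },
        relu = list(dx = dy * cache$pos, grads = NULL),
        lrelu = {
            dx <- dy * ifelse(cache$pos, 1, layer$slope)
            dim(dx) <- dim(dy)
            list(dx = dx, grads = NULL)
        },
        tanh = list(dx = dy * (1 - cache$y^2), grads = NULL),
        sigmoid = list(dx = dy * cache$y * (1 - cache$y), grads = NULL),
        upsample2x = list(dx = .upsample2xGrad(dy, cache$hw), grads = NULL),
        resblock = {
            res <- .netBackward(layer$layers, cache, dy)
            list(dx = dy + res$dx, grads = res$grads)
        },
        stop("unknown layer type ", layer$type)
    )
}

.netForward <- function(layers, x, train = TRUE) {
    caches <- vector("list", length(layers))
    for (i in seq_along(layers)) {
        res <- .layerForward(layers[[i]], x, train = train)
        x <- res$y
        caches[i] <- list(res$cache)    # keep NULL slots in place
    }
    list(y = x, caches = caches)
}

.netBackward <- function(layers, caches, dy) {
    grads <- vector("list", length(layers))
    for (i in rev(seq_along(layers))) {
        res <- .layerBackward(layers[[i]], caches[[i]], dy)
        dy <- res$dx
        grads[i] <- list(res$grads)     # keep NULL slots in place
    }
    list(dx = dy, grads = grads)
}

## Elementwise sum of two (possibly nested, e.g. residual-block) gradient
## lists with the same structure.
.netAccumulate <- function(g1, g2) {
    if (is.null(g1)) return(g2)
    if (is.null(g2)) return(g1)
    if (is.numeric(g1)) return(g1 + g2)
    for (i in seq_along(g2))
        g1[i] <- list(.netAccumulate(g1[[i]], g2[[i]]))
    g1
}

.paramNames <- function(layer)
    switch(layer$type,
           conv = c("W", "b"),
           inorm = c("gamma", "beta"),
           character(0))

.netAdamInit <- function(layers) {
    lapply(layers, function(l) {
        if (l$type == "resblock") list(sub = .netAdamInit(l$layers))
        else {
            pn <- .paramNames(l)
            if (!length(pn)) NULL
            else lapply(stats::setNames(l[pn], pn), function(p)
                list(m = 0 * as.array(p), v = 0 * as.array(p)))
        }
    })
}

.netAdamStep <- function(layers, grads, state, lr, t,
                         beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
    for (i in seq_along(layers)) {
        l <- layers[[i]]
        if (l$type == "resblock") {
            ## grads[[i]] is the sub-layer grads list
            res <- .netAdamStep(l$layers, grads[[i]], state[[i]]$sub,
                                lr, t, beta1, beta2, eps)
            layers[[i]]$layers <- res$layers
            state[[i]]$sub <- res$state
        } else {
            pn <- .paramNames(l)
            if (!length(pn) || is.null(grads[[i]])) next
            for (nm in pn) {
                g <- grads[[i]][[nm]]
                if (is.null(g)) next
                upd <- .adamUpdate(l[[nm]], g, state[[i]][[nm]],
                                   lr, beta1, beta2, eps, t)
                layers[[i]][[nm]] <- upd$p
                state[[i]][[nm]] <- upd$st
            }
        }
    }
    list(layers = layers, state = state)
}
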