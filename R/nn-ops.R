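## Minimal convolutional-network engine with manual backpropagation.
## Feature maps are [H, W, C] double arrays; conv weights are [kh, kw,
## cin, cout]. Convolution runs as a cached-index im2col gather followed
## by a BLAS gemm; the data gradient is the transposed convolution
## (stride-dilated output gradient convolved with the flipped kernel).

.im2colCache <- new.env(parent = emptyenv())

.im2colIndex <- function(H, W, C, kh, kw, stride) {
    key <- paste(H, W, C, kh, kw, stride, sep = "_")
    hit <- .im2colCache[[key]]
    if (!is.null(hit)) return(hit)
    Hout <- (H - kh) %/% stride + 1L
    Wout <- (W - kw) %/% stride + 1L
    pi <- rep((seq_len(Hout) - 1L) * stride, times = Wout)
    pj <- rep((seq_len(Wout) - 1L) * stride, each = Hout)
    K <- kh * kw * C
    kiv <- rep(seq_len(kh), times = kw * C)
    kjv <- rep(rep(seq_len(kw), each = kh), times = C)
    cv <- rep(seq_len(C), each = kh * kw)
    idx <- outer(pi, kiv, "+") +
        outer(pj, (kjv - 1L), "+") * H +
        matrix((cv - 1L) * H * W, Hout * Wout, K, byrow = TRUE)
    out <- list(idx = idx, Hout = Hout, Wout = Wout)
    .im2colCache[[key]] <- out
    out
}

.padZero <- function(x, p) {
    if (p == 0L) return(x)
    d <- dim(x)
    out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
    out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
    out
}

.reflectIdx <- function(n, p) c((p + 1):2, seq_len(n), (n - 1):(n - p))

.padReflect <- function(x, p) {
    if (p == 0L) return(x)
    d <- dim(x)
    x[.reflectIdx(d[1], p), .reflectIdx(d[2], p), , drop = FALSE]
}

.unpadZeroGrad <- function(dxp, p) {
    if (p == 0L) return(dxp)
    d <- dim(dxp)
    dxp[p + seq_len(d[1] - 2 * p), p + seq_len(d[2] - 2 * p), , drop = FALSE]
}

.reflectMatCache <- new.env(parent = emptyenv())

.reflectMat <- function(n, p) {
    key <- paste(n, p, sep = "_")
    hit <- .reflectMatCache[[key]]
    if (!is.null(hit)) return(hit)
    ref <- .reflectIdx(n, p)
    M <- matrix(0, n + 2 * p, n)
    M[cbind(seq_along(ref), ref)] <- 1
    .reflectMatCache[[key]] <- M
    M
}

.unpadReflectGrad <- function(dxp, p) {
    if (p == 0L) return(dxp)
    d <- dim(dxp)
    Mh <- .reflectMat(d[1] - 2 * p, p)
    Mw <- .reflectMat(d[2] - 2 * p, p)
    out <- array(0, c(d[1] - 2 * p, d[2] - 2 * p, d[3]))
    for (c in seq_len(d[3]))
        out[, , c] <- crossprod(Mh, dxp[, , c]) %*% Mw
    out
}

## Convolution on an already-padded input.
.convForwardRaw <- function(xp, Wmat, bias, kh, kw, stride, keep = TRUE) {
    d <- dim(xp)
    ic <- .im2colIndex(d[1], d[2], d[3], kh, kw, stride)
    Xcol <- xp[ic$idx]
    dim(Xcol) <- dim(ic$idx)
    Y <- Xcol %*% Wmat
    Y <- sweep(Y, 2, bias, "+")
    y <- array(Y, c(ic$Hout, ic$Wout, length(bias)))
    list(y = y, Xcol = if (keep) Xcol else NULL)
}

.convBackwardRaw <- function(dy, Xcol, Warr, xpDim, stride) {
    kh <- dim(Warr)[1]; kw <- dim(Warr)[2]
    cin <- dim(Warr)[3]; cout <- dim(Warr)[4]
    dyd <- dim(dy)
    dYmat <- matrix(dy, dyd[1] * dyd[2], cout)
    dW <- crossprod(Xcol, dYmat)
    dim(dW) <- dim(Warr)
    db <- colSums(dYmat)
    ## data gradient: dilate dy by stride, pad by k-1, convolve with the
    ## spatially flipped, channel-transposed kernel
    Hd <- (dyd[1] - 1L) * stride + 1L
    Wd <- (dyd[2] - 1L) * stride + 1L
    z <- array(0, c(Hd, Wd, cout))
    z[seq(1L, Hd, by = stride), seq(1L, Wd, by = stride), ] <- dy
    zp <- array(0, c(Hd + 2 * (kh - 1L), Wd + 2 * (kw - 1L), cout))
    zp[(kh - 1L) + seq_len(Hd), (kw - 1L) + seq_len(Wd), ] <- z
    Wt <- aperm(Warr[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
    Wtmat <- matrix(Wt, kh * kw * cout, cin)
    res <- .convForwardRaw(zp, Wtmat, numeric(cin), kh, kw, 1L, keep = FALSE)
    dxp <- res$y
    ## rows/cols beyond the last stride step receive no gradient
    if (any(dim(dxp)[1:2] < xpDim[1:2])) {
        full <- array(0, c(xpDim[1:2], cin))
        full[seq_len(dim(dxp)[1]), seq_len(dim(dxp)[2]), ] <- dxp
        dxp <- full
    }
    list(dx = dxp, dW = dW, db = db)
}

.instNormForward <- function(x, gamma, beta, eps = 1e-5) {
    d <- dim(x)
    xm <- matrix(x, d[1] * d[2], d[3])
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu, "-")
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, invstd, "*")
    y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    list(y = array(y, d), xhat = xhat, invstd = invstd)
}

.instNormBackward <- function(dy, cache, gamma) {
    d <- dim(dy)
    dym <- matrix(dy, d[1] * d[2], d[3])
    xhat <- cache$xhat
    dg <- colSums(dym * xhat)
    db <- colSums(dym)
    dxhat <- sweep(dym, 2, gamma, "*")
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*")
    dx <- sweep(dx, 2, cache$invstd, "*")
    list(dx = array(dx, d), dg = dg, db = db)
}

.upsample2x <- function(x) {
    d <- dim(x)
    out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
    for (c in seq_len(d[3]))
        out[, , c] <- .bilinearResize(x[, , c, drop = TRUE], 2 * d[1], 2 * d[2])
    out
}

.upsample2xGrad <- function(dy, hw) {
    d <- dim(dy)
    out <- array(0, c(hw[1], hw[2], d[3]))
    for (c in seq_len(d[3]))
        out[, , c] <- .bilinearResizeAdjoint(
            array(dy[, , c], d[1:2]), hw[1], hw[2])
    out
}

## ---- Adam -------------------------------------------------------------

.adamInitFromParams <- function(params) {
    lapply(params, function(p) {
        if (is.null(p)) NULL
        else list(m = array(0, dim(as.array(p))), v = array(0, dim(as.array(p))))
    })
}

.adamUpdate <- function(p, g, st, lr, beta1, beta2, eps, t) {
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}
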