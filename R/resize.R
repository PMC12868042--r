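## Bilinear resize as two separable interpolation matrices. Output pixel
## centre i (0-based) samples source coordinate (i + 0.5) * nIn/nOut - 0.5
## (FOV centres aligned), clamped to the grid. nIn == nOut gives the exact
## identity. The linear form y = Rh x Rw' makes the adjoint (needed for
## backpropagation through the generator's upsampling layers) a transpose.

.resizeCache <- new.env(parent = emptyenv())

.resizeMatrix <- function(nIn, nOut) {
    key <- paste0(nIn, "_", nOut)
    hit <- .resizeCache[[key]]
    if (!is.null(hit)) return(hit)
    i <- seq_len(nOut) - 1
    s <- (i + 0.5) * nIn / nOut - 0.5
    s <- pmin(pmax(s, 0), nIn - 1)
    i0 <- floor(s)
    w1 <- s - i0
    i0 <- pmin(i0, nIn - 2)              # keep i0+1 in range; w adjusts
    w1 <- s - i0
    R <- matrix(0, nOut, nIn)
    R[cbind(seq_len(nOut), i0 + 1)] <- 1 - w1
    R[cbind(seq_len(nOut), i0 + 2)] <- R[cbind(seq_len(nOut), i0 + 2)] + w1
    if (nIn == 1L) R <- matrix(1, nOut, 1)
    .resizeCache[[key]] <- R
    R
}

.bilinearResize <- function(mat, h2, w2) {
    h1 <- nrow(mat); w1 <- ncol(mat)
    if (h1 == h2 && w1 == w2) return(mat)
    .resizeMatrix(h1, h2) %*% mat %*% t(.resizeMatrix(w1, w2))
}

## Adjoint of .bilinearResize with respect to its input (for gradients).
.bilinearResizeAdjoint <- function(dy, h1, w1) {
    h2 <- nrow(dy); w2 <- ncol(dy)
    if (h1 == h2 && w1 == w2) return(dy)
    t(.resizeMatrix(h1, h2)) %*% dy %*% .resizeMatrix(w1, w2)
}

.nearestIndexMap <- function(nIn, nOut) {
    i <- seq_len(nOut) - 1
    s <- (i + 0.5) * nIn / nOut - 0.5
    pmin(pmax(round(s), 0), nIn - 1) + 1
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Resample a volume in-plane to a new pixel spacing
#'
#' The slice axis is untouched. The output in-plane grid size is
#' \code{round(oldSize * oldSpacing / newSpacing)} per axis with halves
#' rounded away from zero, so a 370-pixel plane at 1 mm resampled to
#' 1.0625 mm becomes 348 pixels. Scalar volumes are interpolated
#' bilinearly, label volumes by nearest neighbour.
#'
#' @param vol a \linkS4class{ScanVolume} or \linkS4class{LabelVolume}.
#' @param newSpacingRC target in-plane spacing in mm, length 2
#'   (row, col) or a single value used for both.
#' @return Object of the same class with updated geometry.
#' @examples
#' v <- ScanVolume(array(0, c(1, 370, 370)), spacing = c(2, 1, 1))
#' dim(voxelData(resampleInplane(v, 1.0625)))   # 1 348 348
#' @export
resampleInplane <- function(vol, newSpacingRC) {
    newSpacingRC <- rep(as.numeric(newSpacingRC), length.out = 2)
    if (any(!is.finite(newSpacingRC)) || any(newSpacingRC <= 0))
        stop("new spacing must be strictly positive")
    isLabel <- is(vol, "LabelVolume")
    arr <- voxelData(vol)
    sp <- voxelSpacing(vol)
    d <- dim(arr)
    newRC <- as.integer(.roundHalfAway(d[2:3] * sp[2:3] / newSpacingRC))
    if (any(newRC < 1)) stop("resampled size collapsed below one pixel")
    out <- array(if (isLabel) 0L else 0, dim = c(d[1], newRC))
    if (isLabel) {
        ri <- .nearestIndexMap(d[2], newRC[1])
        ci <- .nearestIndexMap(d[3], newRC[2])
        for (k in seq_len(d[1])) {
            sl <- array(arr[k, , ], dim = d[2:3])
            out[k, , ] <- sl[ri, ci, drop = FALSE]
        }
    } else {
        for (k in seq_len(d[1])) {
            sl <- array(arr[k, , ], dim = d[2:3])
            out[k, , ] <- .bilinearResize(sl, newRC[1], newRC[2])
        }
    }
    newSp <- c(sp[1], newSpacingRC)
    if (isLabel)
        LabelVolume(out, spacing = newSp)
    else
        ScanVolume(out, spacing = newSp, modality = modality(vol),
                   intensityRange = intensityRange(vol))
}
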