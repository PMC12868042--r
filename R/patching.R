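## Patch origin lattice: 0, s, 2s, ... while origin + patch <= dim, plus a
## final clamped origin at (dim - patch) when the lattice misses the edge.
## This reproduces the canonical 9-patch tiling of a 348x348 slice with
## 220x220 patches at stride 64 (origins {0, 64, 128}, 128 + 220 = 348)
## and guarantees full coverage for arbitrary sizes.
.originLattice <- function(dimSize, patchSize, stride) {
    if (patchSize > dimSize)
        stop("patch size ", patchSize, " exceeds slice dimension ", dimSize)
    last <- dimSize - patchSize
    org <- seq(0L, last, by = stride)
    if (org[length(org)] != last) org <- c(org, last)
    as.integer(org)
}

.gridFromOrigins <- function(arr, slices, originsRC, patchSize) {
    patches <- list()
    origins <- matrix(0L, 0, 3,
                      dimnames = list(NULL, c("slice", "row0", "col0")))
    n <- 0L
    for (i in seq_along(slices)) {
        k <- slices[i]
        o <- originsRC[[i]]
        for (r in seq_len(nrow(o))) {
            n <- n + 1L
            patches[[n]] <- array(
                arr[k, o[r, 1] + seq_len(patchSize), o[r, 2] + seq_len(patchSize)],
                dim = c(patchSize, patchSize))
            origins <- rbind(origins, c(k - 1L, o[r, 1], o[r, 2]))
        }
    }
    new("PatchGrid", patches = patches, origins = origins,
        patchSize = as.integer(patchSize), sourceDim = dim(arr))
}

#' Candidate patch origins for one axis
#'
#' Exposed for inspection: the stride lattice plus the clamped final
#' origin.
#'
#' @param dimSize axis length in pixels.
#' @param patchSize patch side.
#' @param stride stride in pixels.
#' @return Integer vector of 0-based origins.
#' @export
patchOriginsForAxis <- function(dimSize, patchSize, stride)
    .originLattice(dimSize, patchSize, stride)

#' Randomly select training patches from every axial slice
#'
#' Candidate origins form the stride lattice (plus the clamped final
#' origin); \code{perSlice} candidates are drawn uniformly without
#' replacement per slice (all of them when fewer exist). With a body mask,
#' candidates whose foreground fraction is below \code{minForeground} are
#' discarded first, mirroring the practice of avoiding patches that are
#' mostly background. Deterministic per seed.
#'
#' @param vol a \linkS4class{ScanVolume} (typically normalized).
#' @param patchSize patch side in pixels (e.g. 220 for CT, 200 for MRI).
#' @param stride stride in pixels (e.g. 64 for phantoms, 32 for patients).
#' @param perSlice patches kept per slice (default 4).
#' @param seed integer seed.
#' @param mask optional \linkS4class{BodyMask} for the foreground filter.
#' @param minForeground minimum in-mask fraction for a candidate (default
#'   0.2; only used when \code{mask} is given).
#' @return A \linkS4class{PatchGrid}.
#' @export
extractTrainingPatches <- function(vol, patchSize, stride, perSlice = 4L,
                                   seed = 1L, mask = NULL,
                                   minForeground = 0.2) {
    arr <- voxelData(vol)
    d <- dim(arr)
    if (perSlice < 1L) stop("perSlice must be >= 1")
    rows <- .originLattice(d[2], patchSize, stride)
    cols <- .originLattice(d[3], patchSize, stride)
    cand <- as.matrix(expand.grid(row0 = rows, col0 = cols))
    m <- if (is.null(mask)) NULL else voxelData(mask)
    .withSeed(seed, {
        originsRC <- vector("list", d[1])
        for (k in seq_len(d[1])) {
            ok <- cand
            if (!is.null(m)) {
                frac <- apply(cand, 1, function(o)
                    mean(m[k, o[1] + seq_len(patchSize),
                           o[2] + seq_len(patchSize)]))
                if (any(frac >= minForeground))
                    ok <- cand[frac >= minForeground, , drop = FALSE]
            }
            take <- min(perSlice, nrow(ok))
            originsRC[[k]] <- ok[sample.int(nrow(ok), take), , drop = FALSE]
        }
        .gridFromOrigins(arr, seq_len(d[1]), originsRC, patchSize)
    })
}

#' Resize a square patch bilinearly
#'
#' Used to bring native patches (e.g. 220 x 220) to the network input size
#' (256 x 256) and back. Bilinear weights are convex, so output values
#' stay within the input range; resizing to the input size is the
#' identity.
#'
#' @param patch square numeric matrix.
#' @param size target side in pixels.
#' @return \code{size} x \code{size} matrix.
#' @export
resizePatch <- function(patch, size) {
    if (nrow(patch) != ncol(patch)) stop("patch must be square")
    .bilinearResize(patch, size, size)
}

#' Deterministic tiling of one slice for inference
#'
#' The full origin lattice (with clamped final origins), guaranteeing that
#' every pixel is covered by at least one patch.
#'
#' @param slice2d numeric matrix (one axial slice).
#' @param patchSize patch side in pixels.
#' @param stride stride in pixels.
#' @return A \linkS4class{PatchGrid} with a single-slice source.
#' @examples
#' g <- tileForInference(matrix(0, 348, 348), 220, 64)
#' length(g)   # 9
#' @export
tileForInference <- function(slice2d, patchSize, stride) {
    arr <- array(slice2d, dim = c(1L, nrow(slice2d), ncol(slice2d)))
    rows <- .originLattice(nrow(slice2d), patchSize, stride)
    cols <- .originLattice(ncol(slice2d), patchSize, stride)
    o <- as.matrix(expand.grid(row0 = rows, col0 = cols))
    .gridFromOrigins(arr, 1L, list(o), patchSize)
}

#' Mean fusion of (predicted) patches back onto the source slice
#'
#' Every output pixel is the average of all patch values covering it.
#' With pass-through predictions this reproduces the tiled slice exactly
#' (partition-of-unity identity).
#'
#' @param grid a \linkS4class{PatchGrid} from [tileForInference()].
#' @param predicted list of matrices at the grid's native patch size, one
#'   per patch; default: the grid's own patches.
#' @return Fused numeric matrix with the source slice dimensions.
#' @export
fuseMean <- function(grid, predicted = patchData(grid)) {
    if (length(predicted) != length(grid))
        stop("need exactly one prediction per patch (",
             length(predicted), " vs ", length(grid), ")")
    d <- grid@sourceDim
    p <- grid@patchSize
    ## incremental (running) mean: m <- m + (x - m)/k. Equivalent to the
    ## arithmetic mean but exactly the identity when all contributions to
    ## a pixel are equal, which keeps pass-through fusion bit-exact.
    m <- matrix(0, d[2], d[3])
    cnt <- matrix(0, d[2], d[3])
    org <- patchOrigins(grid)
    for (i in seq_along(predicted)) {
        pr <- predicted[[i]]
        if (!all(dim(pr) == c(p, p)))
            stop("prediction ", i, " is not at the native patch size")
        ri <- org[i, 2] + seq_len(p)
        ci <- org[i, 3] + seq_len(p)
        cnt[ri, ci] <- cnt[ri, ci] + 1
        m[ri, ci] <- m[ri, ci] + (pr - m[ri, ci]) / cnt[ri, ci]
    }
    if (any(cnt == 0))
        stop("mean fusion found uncovered pixels (grid does not tile the slice)")
    m
}
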