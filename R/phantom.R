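## Desk-scale stand-in for a licensed NURBS anatomy library: parametric
## abdominal geometry (analytic ellipsoids and tubes) rendered to perfectly
## aligned piecewise-constant CT / MRI volumes, plus patient-like
## degradations (correlated noise, bias field, texture) that create the
## "patient" domain for unpaired training at desk scale.

#' PhantomSpec: parametric abdominal phantom geometry
#'
#' @slot gridDim integer length-3 (slice, row, col).
#' @slot spacing voxel spacing in mm.
#' @slot organs organ names drawn from body, lungs, liver, spine, aorta,
#'   bowel.
#' @slot jitter relative random perturbation of organ positions/radii
#'   (deterministic per seed).
#' @slot seed integer random seed fixing the geometry.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(gridDim = "integer", spacing = "numeric",
                   organs = "character", jitter = "numeric",
                   seed = "integer"),
    prototype(gridDim = c(24L, 128L, 128L), spacing = c(2, 1, 1),
              organs = c("body", "lungs", "liver", "spine", "aorta", "bowel"),
              jitter = 0.05, seed = 1L)
)

setValidity("PhantomSpec", function(object) {
    if (length(object@gridDim) != 3L || object@gridDim[1] < 1L ||
        any(object@gridDim[2:3] < 16L))
        return("gridDim needs >= 1 slice and in-plane sizes >= 16")
    if (!"body" %in% object@organs)
        return("the body outline is mandatory")
    if (object@jitter < 0 || object@jitter > 0.2)
        return("jitter must lie in [0, 0.2]")
    TRUE
})

#' Construct a PhantomSpec
#' @param gridDim grid size (slice, row, col); default 24 x 128 x 128.
#' @param spacing voxel spacing in mm; default c(2, 1, 1).
#' @param organs organ subset to include (body is mandatory).
#' @param jitter relative geometric jitter, default 0.05.
#' @param seed integer seed, default 1.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(gridDim = c(24L, 128L, 128L), spacing = c(2, 1, 1),
                        organs = c("body", "lungs", "liver", "spine",
                                   "aorta", "bowel"),
                        jitter = 0.05, seed = 1L) {
    new("PhantomSpec", gridDim = as.integer(gridDim),
        spacing = as.numeric(spacing), organs = organs,
        jitter = as.numeric(jitter), seed = as.integer(seed))
}

#' DegradationSpec: patient-like degradation parameters
#'
#' @slot noiseSigma stationary noise standard deviation (HU or a.u.).
#' @slot corrLen in-plane Gaussian correlation length of the noise in
#'   voxels (0 = white noise).
#' @slot biasAmp relative amplitude of a smooth multiplicative bias field.
#' @slot biasCells coarse control-grid size of the bias field.
#' @slot textureAmp per-organ texture amplitude (same units as the image;
#'   applied only when an organ label map is supplied).
#' @exportClass DegradationSpec
setClass("DegradationSpec",
    representation(noiseSigma = "numeric", corrLen = "numeric",
                   biasAmp = "numeric", biasCells = "integer",
                   textureAmp = "numeric"),
    prototype(noiseSigma = 20, corrLen = 1.5, biasAmp = 0.05,
              biasCells = 4L, textureAmp = 0)
)

setValidity("DegradationSpec", function(object) {
    if (object@noiseSigma < 0 || object@corrLen < 0 ||
        object@biasAmp < 0 || object@textureAmp < 0)
        return("all degradation amplitudes must be >= 0")
    TRUE
})

#' Construct a DegradationSpec
#'
#' Defaults emulate abdominal patient CT texture: noise standard deviation
#' 20 HU with a 1.5-voxel correlation length and a 5\% smooth bias field.
#'
#' @param noiseSigma noise SD (HU or a.u.), default 20.
#' @param corrLen noise correlation length in voxels, default 1.5.
#' @param biasAmp relative bias-field amplitude, default 0.05.
#' @param biasCells bias control grid cells per axis, default 4.
#' @param textureAmp per-organ texture amplitude, default 0.
#' @return A \linkS4class{DegradationSpec}.
#' @export
DegradationSpec <- function(noiseSigma = 20, corrLen = 1.5, biasAmp = 0.05,
                            biasCells = 4L, textureAmp = 0) {
    new("DegradationSpec", noiseSigma = noiseSigma, corrLen = corrLen,
        biasAmp = biasAmp, biasCells = as.integer(biasCells),
        textureAmp = textureAmp)
}

## Organ label codes.
.organLabels <- c(body = 1L, lungL = 2L, lungR = 3L, liver = 4L,
                  spine = 5L, aorta = 6L, bowel = 7L)

#' Default tissue lookup table
#'
#' Linear attenuation coefficients at 120 keV (1/cm) for the organs of the
#' synthetic phantom, together with VIBE-like MRI intensities (a.u.).
#' Label 0 is air. With muWater = 0.1615 1/cm the implied CT numbers are
#' approximately: soft tissue +40 HU, lung -700 HU, liver +56 HU, bone
#' +733 HU, blood +31 HU, bowel -31 HU.
#'
#' @param muWater water attenuation at 120 keV (1/cm), default 0.1615.
#' @return A \linkS4class{TissueTable}.
#' @export
defaultTissueTable <- function(muWater = 0.1615) {
    tb <- data.frame(
        label = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L),
        name = c("air", "soft_tissue", "lung_left", "lung_right",
                 "liver", "bone", "blood", "bowel"),
        mu_120kev = c(0, 0.1680, 0.0485, 0.0485, 0.1705, 0.2799,
                      0.1665, 0.1565),
        mri_intensity = c(0, 120, 15, 15, 140, 60, 180, 90),
        stringsAsFactors = FALSE
    )
    TissueTable(tb, muWater = muWater)
}

## Evaluate with a private RNG stream so callers' RNG state is untouched.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

.ellipsoidMask <- function(coords, center, semi) {
    ## coords: list of Z, R, C arrays in [0,1] x [-1,1] x [-1,1]
    q <- ((coords$Z - center[1]) / semi[1])^2 +
         ((coords$R - center[2]) / semi[2])^2 +
         ((coords$C - center[3]) / semi[3])^2
    q <= 1
}

.coordArrays <- function(d) {
    z <- (seq_len(d[1]) - 0.5) / d[1]
    r <- 2 * (seq_len(d[2]) - 0.5) / d[2] - 1
    cc <- 2 * (seq_len(d[3]) - 0.5) / d[3] - 1
    list(Z = array(rep(z, times = d[2] * d[3]), d),
         R = array(rep(rep(r, each = d[1]), times = d[3]), d),
         C = array(rep(cc, each = d[1] * d[2]), d))
}

#' Generate the organ label volume of a synthetic phantom
#'
#' Deterministic for a given spec (geometry jitter is driven by the spec
#' seed). Row coordinates run anterior (low row) to posterior (high row).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{LabelVolume}.
#' @examples
#' lab <- makeLabels(PhantomSpec(gridDim = c(8L, 64L, 64L)))
#' table(voxelData(lab))
#' @export
makeLabels <- function(spec) {
    validObject(spec)
    d <- spec@gridDim
    .withSeed(spec@seed, {
        j <- function(x) x * (1 + stats::runif(length(x), -spec@jitter,
                                               spec@jitter))
        co <- .coordArrays(d)
        lab <- array(0L, d)

        bodySemi <- j(c(10, 0.78, 0.88))   # effectively all slices
        body <- .ellipsoidMask(co, c(0.5, 0, 0), bodySemi)
        lab[body] <- .organLabels["body"]

        organMask <- function(center, semi) {
            m <- .ellipsoidMask(co, center, semi)
            if (any(m & !body))
                stop("phantom spec error: organ exceeds the body outline")
            m
        }

        if ("lungs" %in% spec@organs) {
            lab[organMask(j(c(0.18, -0.12, -0.38)), j(c(0.22, 0.34, 0.26)))] <-
                .organLabels["lungL"]
            lab[organMask(j(c(0.18, -0.12, 0.38)), j(c(0.22, 0.34, 0.28)))] <-
                .organLabels["lungR"]
        }
        if ("liver" %in% spec@organs)
            lab[organMask(j(c(0.48, -0.08, 0.34)), j(c(0.20, 0.38, 0.38)))] <-
                .organLabels["liver"]
        if ("bowel" %in% spec@organs) {
            lab[organMask(j(c(0.78, -0.15, -0.22)), j(c(0.16, 0.30, 0.30)))] <-
                .organLabels["bowel"]
            lab[organMask(j(c(0.85, 0.05, 0.18)), j(c(0.12, 0.22, 0.26)))] <-
                .organLabels["bowel"]
        }
        if ("aorta" %in% spec@organs)
            lab[organMask(j(c(0.5, 0.28, -0.06)), c(10, j(0.06), j(0.06)))] <-
                .organLabels["aorta"]
        if ("spine" %in% spec@organs)
            lab[organMask(j(c(0.5, 0.52, 0)), c(10, j(0.14), j(0.12)))] <-
                .organLabels["spine"]

        present <- setdiff(intersect(spec@organs, names(.organLabels)),
                           character(0))
        LabelVolume(lab, spacing = spec@spacing)
    })
}

#' Convert a linear attenuation coefficient to a CT number
#'
#' \code{HU = 1000 * (mu - muWater) / muWater}: water maps to 0 HU, air
#' (mu = 0) to -1000 HU.
#'
#' @param mu attenuation coefficient(s), 1/cm.
#' @param muWater water attenuation, 1/cm (> 0).
#' @return CT number(s) in HU.
#' @export
muToHU <- function(mu, muWater = 0.1615) {
    if (muWater <= 0) stop("muWater must be positive")
    1000 * (mu - muWater) / muWater
}

.lookupRender <- function(labels, tissues, column, background) {
    lab <- voxelData(labels)
    tb <- tissues@table
    labsPresent <- sort(unique(as.vector(lab)))
    unknown <- setdiff(labsPresent, c(0L, tb$label))
    if (length(unknown))
        stop("labels missing from the tissue table: ",
             paste(unknown, collapse = ", "))
    lut <- rep(background, max(labsPresent) + 1L)
    idx <- match(tb$label, seq(0L, max(labsPresent)) )
    keep <- !is.na(idx)
    lut[tb$label[keep] + 1L] <- tb[[column]][keep]
    lut[1L] <- background                      # label 0 is always background
    array(lut[lab + 1L], dim(lab))
}

#' Render a piecewise-constant CT volume from organ labels
#'
#' Each label receives the CT number implied by its attenuation
#' coefficient; the background (label 0) is air at -1000 HU.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param tissues a \linkS4class{TissueTable} covering all labels.
#' @return A CT \linkS4class{ScanVolume} with intensity range
#'   (-1000, 1047).
#' @export
renderCT <- function(labels, tissues) {
    tb <- tissues@table
    hu <- muToHU(tb$mu_120kev, tissues@muWater)
    tmp <- tissues
    tmp@table$hu <- hu
    arr <- .lookupRender(labels, tmp, "hu", background = -1000)
    ScanVolume(arr, spacing = voxelSpacing(labels), modality = "CT",
               intensityRange = c(.CT_LO, .CT_HI))
}

#' Render a piecewise-constant MRI volume from organ labels
#'
#' Per-tissue intensity lookup (VIBE-like contrast); background 0. The CT
#' and MRI renderings of one label volume are voxelwise co-registered by
#' construction.
#'
#' @inheritParams renderCT
#' @return An MRI \linkS4class{ScanVolume}.
#' @export
renderMRI <- function(labels, tissues) {
    arr <- .lookupRender(labels, tissues, "mri_intensity", background = 0)
    ScanVolume(arr, spacing = voxelSpacing(labels), modality = "MRI")
}

.smoothNoise <- function(d, corrLen) {
    n <- array(stats::rnorm(prod(d)), d)
    if (corrLen > 0) {
        for (k in seq_len(d[1])) {
            sl <- array(n[k, , ], dim = d[2:3])
            n[k, , ] <- EBImage::gblur(sl, sigma = corrLen)
        }
    }
    n
}

#' Apply patient-like degradations to a clean volume
#'
#' Adds stationary correlated Gaussian noise (Gaussian-filtered white noise
#' rescaled to the requested SD), a smooth multiplicative bias field, and
#' optional per-organ texture. Deterministic for a given seed.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param spec a \linkS4class{DegradationSpec}.
#' @param seed integer seed.
#' @param labels optional \linkS4class{LabelVolume} enabling per-organ
#'   texture.
#' @return Degraded \linkS4class{ScanVolume}.
#' @export
degradeVolume <- function(vol, spec, seed = 1L, labels = NULL) {
    validObject(spec)
    arr <- voxelData(vol)
    d <- dim(arr)
    .withSeed(seed, {
        if (spec@biasAmp > 0) {
            nc <- spec@biasCells
            coarse <- array(stats::runif(nc^3, -1, 1), c(nc, nc, nc))
            field <- .trilinearUpsample(coarse, d)
            arr <- arr * (1 + spec@biasAmp * field)
        }
        if (spec@noiseSigma > 0) {
            noise <- .smoothNoise(d, spec@corrLen)
            noise <- noise / stats::sd(as.vector(noise)) * spec@noiseSigma
            arr <- arr + noise
        }
        if (spec@textureAmp > 0 && !is.null(labels)) {
            lab <- voxelData(labels)
            tex <- .smoothNoise(d, max(spec@corrLen, 1))
            tex <- tex / stats::sd(as.vector(tex))
            arr <- arr + spec@textureAmp * tex * (lab > 0)
        }
        ScanVolume(arr, spacing = voxelSpacing(vol),
                   modality = modality(vol),
                   intensityRange = intensityRange(vol))
    })
}

.trilinearUpsample <- function(coarse, d) {
    cz <- .resizeMatrix(dim(coarse)[1], d[1])
    cr <- .resizeMatrix(dim(coarse)[2], d[2])
    cc <- .resizeMatrix(dim(coarse)[3], d[3])
    ## separable interpolation: z, then r, then c
    a <- apply(coarse, c(2, 3), function(v) cz %*% v)       # d1 x n2 x n3
    dim(a) <- c(d[1], dim(coarse)[2], dim(coarse)[3])
    b <- array(0, c(d[1], d[2], dim(coarse)[3]))
    for (k in seq_len(dim(coarse)[3]))
        b[, , k] <- array(a[, , k], dim(a)[1:2]) %*% t(cr)
    out <- array(0, d)
    for (k in seq_len(d[1]))
        out[k, , ] <- array(b[k, , ], dim(b)[2:3]) %*% t(cc)
    out
}

#' Simulate a complete desk-scale phantom study
#'
#' One call produces everything the pipeline consumes: the organ label
#' volume, clean piecewise-constant CT and MRI renderings, and their
#' patient-like degraded counterparts forming the unpaired "patient"
#' domain.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param tissues a \linkS4class{TissueTable}; default
#'   [defaultTissueTable()].
#' @param ctDegrade,mriDegrade \linkS4class{DegradationSpec} objects for
#'   the two modalities. Defaults: 20 HU correlated noise for CT, 9 a.u.
#'   for MRI (matching abdominal patient noise levels).
#' @param seed integer seed for the degradations.
#' @return A list with elements \code{labels}, \code{ct}, \code{mri},
#'   \code{patientCT}, \code{patientMRI}, \code{tissues}.
#' @export
simulatePhantomStudy <- function(spec = PhantomSpec(),
                                 tissues = defaultTissueTable(),
                                 ctDegrade = DegradationSpec(noiseSigma = 20),
                                 mriDegrade = DegradationSpec(noiseSigma = 9),
                                 seed = 1L) {
    labels <- makeLabels(spec)
    ct <- renderCT(labels, tissues)
    mri <- renderMRI(labels, tissues)
    list(labels = labels,
         ct = ct,
         mri = mri,
         patientCT = clipCT(degradeVolume(ct, ctDegrade, seed = seed,
                                          labels = labels)),
         patientMRI = degradeVolume(mri, mriDegrade, seed = seed + 1L,
                                    labels = labels),
         tissues = tissues)
}
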