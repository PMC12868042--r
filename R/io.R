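## Axis mapping for on-disk formats: NIfTI / MetaImage store (x, y, z) with x
## fastest; in memory the package uses (slice, row, col) = (z, y, x).

.fromDiskOrder <- function(arr) aperm(arr, c(3, 2, 1))
.toDiskOrder <- function(arr) aperm(arr, c(3, 2, 1))

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI-1 (\code{.nii}, \code{.nii.gz}) and MetaImage
#' (\code{.mha}, \code{.mhd} + raw). The voxel spacing is taken from the
#' file header; a missing or non-positive spacing is an error, never a
#' silent 1 mm assumption. Axes are normalized to (slice, row, col).
#'
#' @param path file path.
#' @param modality modality tag to attach (\code{"CT"}, \code{"MRI"},
#'   \code{"DOSE"}, \code{"GENERIC"}).
#' @return A \linkS4class{ScanVolume}.
#' @seealso [writeVolume()], [readLabelVolume()]
#' @export
readVolume <- function(path, modality = "GENERIC") {
    if (!file.exists(path))
        stop("file not found: ", path)
    lower <- tolower(path)
    if (grepl("\\.nii(\\.gz)?$", lower)) {
        parsed <- .readNiftiVolume(path)
    } else if (grepl("\\.(mha|mhd)$", lower)) {
        parsed <- .readMetaImage(path)
    } else {
        stop("unsupported volume format (need .nii/.nii.gz/.mha/.mhd): ", path)
    }
    ScanVolume(parsed$data, spacing = parsed$spacing, modality = modality)
}

#' Read a label volume (integer organ map)
#'
#' As [readVolume()] but values are rounded to integers and returned as a
#' \linkS4class{LabelVolume}.
#'
#' @param path file path.
#' @return A \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path) {
    v <- readVolume(path)
    LabelVolume(round(voxelData(v)), spacing = voxelSpacing(v))
}

.readNiftiVolume <- function(path) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                        stop("unreadable NIfTI file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
        stop("expected a 3D volume in ", path, " but found ",
             length(dim(arr)), " dimensions")
    sp <- RNifti::pixdim(img)[seq_len(3)]
    if (any(!is.finite(sp)) || any(sp <= 0))
        stop("missing or invalid voxel spacing in NIfTI header of ", path)
    list(data = .fromDiskOrder(arr), spacing = rev(sp))
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Scalar volumes are stored as float32 (value-identical within float32
#' precision on round trip); \linkS4class{LabelVolume} objects as int32
#' (bit-identical round trip). The format follows the file extension.
#'
#' @param vol a \linkS4class{ScanVolume} or \linkS4class{LabelVolume}.
#' @param path output path ending in \code{.nii}, \code{.nii.gz},
#'   \code{.mha} or \code{.mhd}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
    if (!dir.exists(dirname(path)))
        stop("parent directory does not exist: ", dirname(path))
    isLabel <- is(vol, "LabelVolume")
    arr <- voxelData(vol)
    sp <- voxelSpacing(vol)
    lower <- tolower(path)
    if (grepl("\\.nii(\\.gz)?$", lower)) {
        disk <- .toDiskOrder(if (isLabel) arr else arr * 1.0)
        img <- RNifti::asNifti(disk)
        RNifti::pixdim(img) <- rev(sp)
        RNifti::writeNifti(img, path,
                           datatype = if (isLabel) "int32" else "float")
    } else if (grepl("\\.(mha|mhd)$", lower)) {
        .writeMetaImage(arr, sp, path, integer = isLabel)
    } else {
        stop("unsupported volume format for writing: ", path)
    }
    invisible(path)
}

## ---- MetaImage (MET_*) ------------------------------------------------
## Minimal MetaImage support: uncompressed raw element data, LOCAL (.mha)
## or sidecar .raw (.mhd) storage, little-endian.

.metaTypes <- list(
    MET_FLOAT = list(what = "numeric", size = 4L),
    MET_DOUBLE = list(what = "numeric", size = 8L),
    MET_SHORT = list(what = "integer", size = 2L),
    MET_INT = list(what = "integer", size = 4L),
    MET_UCHAR = list(what = "integer", size = 1L),
    MET_USHORT = list(what = "integer", size = 2L)
)

.readMetaImage <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- list()
    repeat {
        line <- readLines(con, n = 1L, warn = FALSE)
        if (length(line) == 0L)
            stop("truncated MetaImage header in ", path)
        kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*)$", line))[[1]]
        if (length(kv) != 3L)
            stop("malformed MetaImage header line in ", path, ": ", line)
        hdr[[kv[2]]] <- trimws(kv[3])
        if (kv[2] == "ElementDataFile") break
    }
    for (key in c("DimSize", "ElementType", "ElementSpacing"))
        if (is.null(hdr[[key]]))
            stop("MetaImage header of ", path, " lacks ", key)
    dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
    if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0))
        stop("MetaImage DimSize must give three positive sizes in ", path)
    sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
    if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
        stop("missing or invalid ElementSpacing in ", path)
    ty <- .metaTypes[[hdr$ElementType]]
    if (is.null(ty))
        stop("unsupported MetaImage ElementType ", hdr$ElementType, " in ", path)
    msb <- identical(hdr$ElementByteOrderMSB, "True") ||
        identical(hdr$BinaryDataByteOrderMSB, "True")
    n <- prod(dims)
    if (identical(hdr$ElementDataFile, "LOCAL")) {
        vals <- readBin(con, ty$what, n = n, size = ty$size,
                        endian = if (msb) "big" else "little",
                        signed = !(hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT")))
    } else {
        rawPath <- file.path(dirname(path), hdr$ElementDataFile)
        if (!file.exists(rawPath))
            stop("MetaImage raw data file not found: ", rawPath)
        rcon <- file(rawPath, "rb")
        on.exit(close(rcon), add = TRUE)
        vals <- readBin(rcon, ty$what, n = n, size = ty$size,
                        endian = if (msb) "big" else "little",
                        signed = !(hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT")))
    }
    if (length(vals) != n)
        stop("truncated MetaImage element data in ", path)
    arr <- array(vals, dim = dims)
    list(data = .fromDiskOrder(arr), spacing = rev(sp))
}

.writeMetaImage <- function(arr, spacing, path, integer = FALSE) {
    disk <- .toDiskOrder(arr)
    dims <- dim(disk)
    type <- if (integer) "MET_INT" else "MET_FLOAT"
    local <- grepl("\\.mha$", tolower(path))
    dataFile <- if (local) "LOCAL" else
        paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
    hdr <- c(
        "ObjectType = Image",
        "NDims = 3",
        "BinaryData = True",
        "BinaryDataByteOrderMSB = False",
        sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
        sprintf("ElementSpacing = %.10g %.10g %.10g",
                spacing[3], spacing[2], spacing[1]),
        sprintf("ElementType = %s", type),
        sprintf("ElementDataFile = %s", dataFile)
    )
    vals <- as.vector(disk)
    if (integer) vals <- as.integer(round(vals))
    con <- file(path, "wb")
    writeLines(hdr, con)
    if (local)
        writeBin(vals, con, size = 4L, endian = "little")
    close(con)
    if (!local) {
        rcon <- file(file.path(dirname(path), dataFile), "wb")
        writeBin(vals, rcon, size = 4L, endian = "little")
        close(rcon)
    }
    invisible(path)
}

## ---- Tissue tables ----------------------------------------------------

#' Read / write tissue lookup tables
#'
#' Plain-text CSV/TSV with header row
#' \code{label,name,mu_120kev,mri_intensity}. Comment lines of the form
#' \code{# key: value} before the header carry metadata; \code{mu_water}
#' (1/cm at 120 keV) is recognized and attached to the returned object.
#'
#' @param path file path (delimiter inferred: tab if any tab on the header
#'   line, comma otherwise).
#' @return A \linkS4class{TissueTable}.
#' @export
readTissueTable <- function(path) {
    if (!file.exists(path)) stop("tissue table not found: ", path)
    lines <- readLines(path)
    meta <- grep("^\\s*#", lines, value = TRUE)
    body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
    body <- body[nzchar(trimws(body))]
    if (!length(body)) stop("empty tissue table: ", path)
    sep <- if (grepl("\t", body[1])) "\t" else ","
    tb <- utils::read.table(text = body, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    muWater <- 0.1615
    for (m in meta) {
        kv <- regmatches(m, regexec("#\\s*([A-Za-z_0-9]+)\\s*[:=]\\s*([-0-9.eE]+)", m))[[1]]
        if (length(kv) == 3L && kv[2] == "mu_water")
            muWater <- as.numeric(kv[3])
    }
    TissueTable(tb, muWater = muWater)
}

#' @rdname readTissueTable
#' @param tissues a \linkS4class{TissueTable} to write.
#' @export
writeTissueTable <- function(tissues, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# mu_water: %.10g", tissues@muWater), con)
    utils::write.csv(tissues@table, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}
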