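#' @useDynLib atlascut, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Seed label codes used in seed label volumes on disk and in memory.
SEED_NONE <- 0L
SEED_ORGAN <- 1L
SEED_BACKGROUND <- 2L

#' 3D scalar volume
#'
#' A minimal container for a 3D image: a numeric array with per-axis voxel
#' spacing (mm) and the physical position of voxel (0,0,0). All algorithms in
#' this package operate in voxel units with 0-based (x, y, z) coordinates,
#' x varying fastest (the array's first index); spacing and origin are carried
#' for I/O fidelity only.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("volume data must be a 3D array with positive extents", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' Binary label mask
#'
#' A {0,1}-valued mask aligned to a [volume3d()]: ground truth or a
#' segmentation result. Shares the volume's shape/spacing/origin contract.
#'
#' @param data 3D array containing only 0 and 1 (logical arrays are coerced).
#' @inheritParams volume3d
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3D array", call. = FALSE)
  if (!all(data %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  v <- volume3d(data, spacing, origin)
  class(v) <- c("label_mask", "volume3d")
  v
}

#' Ternary seed image
#'
#' Per-voxel user annotations: organ seeds, background seeds, or unlabeled.
#' Stored as integer codes (0 = none, 1 = organ, 2 = background). The numeric
#' view used by the atlas-fitting energy maps organ seeds to -1, background
#' seeds to `alpha` and unlabeled voxels to 0 (see [seed_numeric()]).
#'
#' @param data 3D array of integer codes in {0, 1, 2}.
#' @param alpha positive background weighting coefficient (default 1, so organ
#'   and background seeds are weighted symmetrically in the fitting energy).
#' @inheritParams volume3d
#' @return An object of class `seed_image` with fields `data`, `alpha`,
#'   `spacing`, `origin`.
#' @export
seed_image <- function(data, alpha = 1, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("seed data must be a 3D array", call. = FALSE)
  bad <- setdiff(unique(as.vector(data)), c(SEED_NONE, SEED_ORGAN, SEED_BACKGROUND))
  if (length(bad))
    stop("unknown seed label code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  data <- array(as.integer(data), dim = dim(data))
  structure(list(data = data, alpha = alpha, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "seed_image")
}

#' Numeric view of a seed image
#'
#' Maps organ seeds to -1, background seeds to `alpha`, unlabeled voxels to 0.
#' This is the signed weighting the atlas-fitting fidelity energy sums over.
#'
#' @param seeds a [seed_image()].
#' @return 3D numeric array taking values in {-1, alpha, 0}.
#' @export
seed_numeric <- function(seeds) {
  stopifnot(inherits(seeds, "seed_image"))
  out <- array(0, dim = dim(seeds$data))
  out[seeds$data == SEED_ORGAN] <- -1
  out[seeds$data == SEED_BACKGROUND] <- seeds$alpha
  out
}

#' Seed voxel coordinates
#'
#' 0-based (x, y, z) coordinates of the organ and background seed voxels.
#'
#' @param seeds a [seed_image()].
#' @return list with integer matrices `organ` and `background` (n x 3).
#' @export
seed_coords <- function(seeds) {
  stopifnot(inherits(seeds, "seed_image"))
  list(organ = which(seeds$data == SEED_ORGAN, arr.ind = TRUE) - 1L,
       background = which(seeds$data == SEED_BACKGROUND, arr.ind = TRUE) - 1L)
}

#' Check that a seed image can drive fitting/segmentation
#'
#' Fitting the atlas and cutting the graph both require at least one organ and
#' one background seed voxel.
#'
#' @param seeds a [seed_image()].
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_seeds <- function(seeds) {
  stopifnot(inherits(seeds, "seed_image"))
  if (!any(seeds$data == SEED_ORGAN))
    stop("seed image has no organ seed voxels", call. = FALSE)
  if (!any(seeds$data == SEED_BACKGROUND))
    stop("seed image has no background seed voxels", call. = FALSE)
  invisible(TRUE)
}

#' Probabilistic atlas
#'
#' A voxel grid on a fixed lattice where each value is the empirical
#' probability, over training cases, that the voxel lies inside the target
#' organ.
#'
#' @param data 3D array of probabilities in \[0, 1\].
#' @return An object of class `prob_atlas`.
#' @export
prob_atlas <- function(data) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("atlas data must be a 3D array", call. = FALSE)
  if (any(data < 0 | data > 1, na.rm = TRUE) || anyNA(data))
    stop("atlas values must lie in [0, 1]", call. = FALSE)
  structure(list(data = data), class = "prob_atlas")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing (%s) mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' @export
print.seed_image <- function(x, ...) {
  cat(sprintf("<seed_image> %s voxels, %d organ / %d background seeds, alpha = %g\n",
              paste(dim(x$data), collapse = "x"),
              sum(x$data == SEED_ORGAN), sum(x$data == SEED_BACKGROUND),
              x$alpha))
  invisible(x)
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> lattice %s, values in [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

# ---- file I/O --------------------------------------------------------------

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.mha$", low) || grepl("\\.mhd$", low)) return("metaimage")
  stop("unrecognised volume format (expected .nii, .nii.gz, .mha or .mhd): ",
       path, call. = FALSE)
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`, via RNifti) and MetaImage
#' (`.mha` single file, or `.mhd` header with `.raw` payload). Spacing and
#' origin are taken from the file header.
#'
#' @param path path to an existing volume file.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (is.null(d) || length(d) != 3L)
      stop("expected a 3D image, got ", length(d), " dimensions: ", path,
           call. = FALSE)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
    return(volume3d(array(as.numeric(img), dim = d), spacing = sp, origin = org))
  }
  read_metaimage(path)
}

#' Write a 3D volume as NIfTI or MetaImage
#'
#' The element type is chosen from the data unless given: integer-valued data
#' in \[0, 255\] are stored as unsigned 8-bit, other integer-valued data as
#' signed 32-bit, and anything else as 64-bit float, so that a write/read
#' round trip is exact for integer data and within float round-off otherwise.
#'
#' @param vol a [volume3d()] (or [label_mask()]).
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`).
#' @param datatype one of "auto", "uint8", "int32", "float64".
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  stopifnot(inherits(vol, "volume3d"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  datatype <- match.arg(datatype, c("auto", "uint8", "int32", "float64"))
  if (datatype == "auto") {
    x <- vol$data
    intish <- all(is.finite(x)) && all(x == round(x))
    datatype <- if (intish && min(x) >= 0 && max(x) <= 255) "uint8"
    else if (intish && min(x) >= -2^31 && max(x) < 2^31) "int32"
    else "float64"
  }
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    dt <- c(uint8 = "uint8", int32 = "int32", float64 = "double")[[datatype]]
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(4)
    m[1:3, 1:3] <- diag(vol$spacing)
    m[1:3, 4] <- vol$origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path, datatype = dt)
  } else {
    write_metaimage(vol, path, datatype)
  }
  invisible(path)
}

#' Read a ternary seed label volume
#'
#' The persistent seed representation is a label volume with integer codes
#' 0 = unlabeled, 1 = organ, 2 = background, so interactive sessions are
#' reproducible headlessly.
#'
#' @param path path to a label volume (NIfTI or MetaImage).
#' @param alpha background coefficient for the numeric seed view.
#' @return a [seed_image()].
#' @export
read_seeds <- function(path, alpha = 1) {
  vol <- read_volume(path)
  seed_image(vol$data, alpha = alpha, spacing = vol$spacing,
             origin = vol$origin)
}

#' Write a seed image as a label volume
#'
#' @param seeds a [seed_image()].
#' @param path output path (NIfTI or MetaImage).
#' @return invisibly, `path`.
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_image"))
  vol <- volume3d(seeds$data, spacing = seeds$spacing, origin = seeds$origin)
  write_volume(vol, path, datatype = "uint8")
}

#' Coerce a volume to a binary mask
#'
#' @param vol a [volume3d()] whose data contain only 0 and 1.
#' @return a [label_mask()].
#' @export
as_label_mask <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  label_mask(vol$data, spacing = vol$spacing, origin = vol$origin)
}

# ---- MetaImage (.mha / .mhd) -----------------------------------------------
# Minimal MetaImage support: no installed R package reads this format, and the
# header is a flat key = value list followed by a raw block, so a small
# dedicated reader/writer is used.

mha_types <- c(MET_UCHAR = "uint8", MET_CHAR = "int8", MET_SHORT = "int16",
               MET_USHORT = "uint16", MET_INT = "int32", MET_UINT = "uint32",
               MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header: ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line,
                               call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "0")
  if (ndims != 3L)
    stop("expected a 3D image, got NDims = ", ndims, ": ", path, call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  met <- hdr[["ElementType"]] %||% "MET_FLOAT"
  if (!met %in% names(mha_types))
    stop("unsupported MetaImage element type: ", met, call. = FALSE)
  msb <- identical(hdr[["BinaryDataByteOrderMSB"]], "True") ||
    identical(hdr[["ElementByteOrderMSB"]], "True")
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path))
      stop("MetaImage data file not found: ", raw_path, call. = FALSE)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  type <- mha_types[[met]]
  vals <- switch(type,
    uint8 = as.numeric(readBin(raw_con, "integer", n, size = 1, signed = FALSE)),
    int8 = as.numeric(readBin(raw_con, "integer", n, size = 1, signed = TRUE)),
    int16 = as.numeric(readBin(raw_con, "integer", n, size = 2, signed = TRUE,
                               endian = endian)),
    uint16 = as.numeric(readBin(raw_con, "integer", n, size = 2, signed = FALSE,
                                endian = endian)),
    int32 = ,
    uint32 = as.numeric(readBin(raw_con, "integer", n, size = 4,
                                endian = endian)),
    float32 = readBin(raw_con, "double", n, size = 4, endian = endian),
    float64 = readBin(raw_con, "double", n, size = 8, endian = endian))
  if (length(vals) != n)
    stop("MetaImage payload shorter than DimSize implies: ", path,
         call. = FALSE)
  volume3d(array(vals, dim = dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(vol, path, datatype) {
  met <- c(uint8 = "MET_UCHAR", int32 = "MET_INT", float64 = "MET_DOUBLE")[[datatype]]
  is_mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (is_mhd) paste0(sub("\\.mhd$", "", basename(path),
                                     ignore.case = TRUE), ".raw") else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    paste("DimSize =", paste(dim(vol$data), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, trim = TRUE), collapse = " ")),
    paste("Offset =", paste(format(vol$origin, trim = TRUE), collapse = " ")),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("ElementType =", met),
    paste("ElementDataFile =", datafile))
  write_payload <- function(con) {
    if (datatype == "float64") {
      writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
    } else {
      writeBin(as.integer(vol$data), con,
               size = if (datatype == "uint8") 1L else 4L, endian = "little")
    }
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (is_mhd) {
    raw_con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(raw_con), add = TRUE)
    write_payload(raw_con)
  } else {
    write_payload(con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
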