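#' 3D intensity volume with voxel geometry
#'
#' A `volume3d` wraps a 3D numeric array together with its physical voxel
#' geometry. The fixed internal axis order is (slice, row, column) =
#' (anterior to posterior, dorsal to ventral, left to right); files carrying
#' other orders must be permuted by the caller at load.
#'
#' Voxel indices are 0-based in physical conversions: voxel `i` occupies the
#' half-open interval `[origin + i*s, origin + (i+1)*s)` along each axis and
#' its center is `origin + (i + 0.5)*s`.
#'
#' @param data 3D numeric, integer, or logical array (slice, row, column).
#' @param voxel_size_um positive length-3 numeric, micrometres per voxel.
#' @param origin_um length-3 numeric, physical position of the corner of
#'   voxel (0,0,0).
#' @return An object of class `volume3d` with fields `data`,
#'   `voxel_size_um`, `origin_um`.
#' @export
volume3d <- function(data, voxel_size_um = c(1, 1, 1), origin_um = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array")
  voxel_size_um <- as.numeric(voxel_size_um)
  origin_um <- as.numeric(origin_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("volume3d: voxel_size_um must be 3 positive reals")
  if (length(origin_um) != 3L || any(!is.finite(origin_um)))
    stop("volume3d: origin_um must be 3 finite reals")
  if (is.numeric(data) && any(!is.finite(data)))
    stop("volume3d: data must be finite")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 origin_um = origin_um),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, %s um/voxel, %s data\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_um, 4), collapse = "x"),
              typeof(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

is_volume3d <- function(x) inherits(x, "volume3d")

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$voxel_size_um, b$voxel_size_um)) ||
      !isTRUE(all.equal(a$origin_um, b$origin_um)))
    stop("volumes do not share geometry")
  invisible(TRUE)
}

#' Convert physical coordinates to 0-based voxel indices
#'
#' Uses `floor((c - origin) / voxel_size)`: a point anywhere inside a
#' voxel's half-open physical box maps to that voxel.
#'
#' @param volume a [volume3d()].
#' @param coords_um numeric matrix (n x 3) or length-3 vector of physical
#'   coordinates in micrometres.
#' @return integer matrix (n x 3) of 0-based voxel indices.
#' @export
um_to_voxel <- function(volume, coords_um) {
  if (is.null(dim(coords_um))) coords_um <- matrix(coords_um, nrow = 1)
  idx <- sweep(coords_um, 2, volume$origin_um, "-")
  idx <- sweep(idx, 2, volume$voxel_size_um, "/")
  storage.mode(idx) <- "double"
  matrix(as.integer(floor(idx)), ncol = 3)
}

#' Physical center coordinates of 0-based voxel indices
#' @param volume a [volume3d()].
#' @param idx0 integer matrix (n x 3) of 0-based voxel indices.
#' @return numeric matrix (n x 3) of voxel-center coordinates in um.
#' @export
voxel_center_um <- function(volume, idx0) {
  if (is.null(dim(idx0))) idx0 <- matrix(idx0, nrow = 1)
  centers <- sweep(idx0 + 0.5, 2, volume$voxel_size_um, "*")
  sweep(centers, 2, volume$origin_um, "+")
}

## ---------------------------------------------------------------------------
## File formats: TIFF stacks (r-tiff), NIfTI-1 (RNifti) and NRRD.
## NRRD is read/written by a minimal attached-header raw-encoding codec here
## (no NRRD package exists in the R stack used).
## ---------------------------------------------------------------------------

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext,
         tif = , tiff = "tiff-stack",
         nrrd = "nrrd",
         nii = "nifti",
         stop("read_volume: cannot guess format from extension '", ext, "'"))
}

#' Read a 3D volume from TIFF stack, NRRD, or NIfTI-1
#'
#' @param path file path.
#' @param format one of `"auto"`, `"tiff-stack"`, `"nrrd"`, `"nifti"`.
#' @param voxel_size_um optional length-3 override; required for formats
#'   whose header carries no spacing (TIFF).
#' @param origin_um optional origin override (default 0).
#' @return a [volume3d()].
#' @export
read_volume <- function(path, format = "auto", voxel_size_um = NULL,
                        origin_um = c(0, 0, 0)) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  res <- switch(format,
    "tiff-stack" = {
      slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(slices)) slices <- list(slices)
      d <- dim(slices[[1]])
      arr <- array(0, dim = c(length(slices), d[1], d[2]))
      for (s in seq_along(slices)) arr[s, , ] <- slices[[s]]
      if (all(arr == round(arr))) storage.mode(arr) <- "integer"
      list(data = arr, spacing = NULL)
    },
    "nrrd" = read_nrrd_raw(path),
    "nifti" = {
      img <- RNifti::readNifti(path)
      arr <- array(as.vector(img), dim = dim(img))
      if (all(arr == round(arr))) storage.mode(arr) <- "integer"
      list(data = arr, spacing = RNifti::pixdim(img)[1:3])
    },
    stop("read_volume: unknown format '", format, "'"))
  spacing <- if (!is.null(voxel_size_um)) voxel_size_um else res$spacing
  if (is.null(spacing))
    stop("read_volume: no voxel size in ", format,
         " header; supply voxel_size_um")
  volume3d(res$data, voxel_size_um = spacing, origin_um = origin_um)
}

#' Write a 3D volume to TIFF stack, NRRD, or NIfTI-1
#'
#' Integer data round-trip bit-exactly through all three formats. Writing
#' non-integer data with an integer `dtype` is refused rather than silently
#' quantized.
#'
#' @param volume a [volume3d()]; logical data are written as 0/255 uint8.
#' @param path output path (parent directory must exist).
#' @param format one of `"auto"`, `"tiff-stack"`, `"nrrd"`, `"nifti"`.
#' @param dtype `"auto"`, `"uint8"`, `"uint16"`, `"int32"`, or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = "auto", dtype = "auto") {
  stopifnot(is_volume3d(volume))
  if (!dir.exists(dirname(path)))
    stop("write_volume: parent directory does not exist: ", dirname(path))
  if (format == "auto") format <- guess_format(path)
  arr <- volume$data
  if (is.logical(arr)) {
    arr <- array(as.integer(arr) * 255L, dim = dim(arr))
    if (dtype == "auto") dtype <- "uint8"
  }
  integerish <- is.integer(arr) || all(arr == round(arr))
  if (dtype == "auto")
    dtype <- if (!integerish) "double"
             else if (max(arr) <= 255 && min(arr) >= 0) "uint8"
             else if (max(arr) <= 65535 && min(arr) >= 0) "uint16"
             else "int32"
  if (dtype %in% c("uint8", "uint16", "int32") && !integerish)
    stop("write_volume: non-integer data cannot be written as ", dtype,
         " (lossy); use dtype = 'double'")
  switch(format,
    "tiff-stack" = {
      if (dtype == "double") {
        # 32-bit float TIFF; not bit-exact for doubles beyond float precision
        slices <- lapply(seq_len(dim(arr)[1]), function(s) arr[s, , ])
        tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
      } else {
        denom <- c(uint8 = 255, uint16 = 65535)[dtype]
        if (is.na(denom))
          stop("write_volume: TIFF supports uint8/uint16/double only")
        slices <- lapply(seq_len(dim(arr)[1]), function(s) arr[s, , ] / denom)
        tiff::writeTIFF(slices, path,
                        bits.per.sample = if (dtype == "uint8") 8L else 16L,
                        reduce = FALSE)
      }
    },
    "nrrd" = write_nrrd_raw(arr, volume$voxel_size_um, path, dtype),
    "nifti" = {
      nii_type <- c(uint8 = "uint8", uint16 = "uint16", int32 = "int32",
                    double = "double")[dtype]
      attr(arr, "pixdim") <- volume$voxel_size_um
      img <- RNifti::asNifti(arr, datatype = nii_type)
      RNifti::writeNifti(img, path)
    },
    stop("write_volume: unknown format '", format, "'"))
  invisible(path)
}

## minimal NRRD codec: attached header, raw encoding, little endian
nrrd_types <- c(uint8 = "uchar", uint16 = "ushort", int32 = "int",
                double = "double")
nrrd_sizes <- c(uchar = 1L, ushort = 2L, int = 4L, double = 8L)

write_nrrd_raw <- function(arr, spacing, path, dtype) {
  type <- nrrd_types[[dtype]]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(arr), collapse = " ")),
           paste0("spacings: ", paste(spacing, collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con, sep = "\n")
  v <- as.vector(arr)
  if (type == "double") writeBin(as.double(v), con, size = 8, endian = "little")
  else writeBin(as.integer(v), con, size = nrrd_sizes[[type]], endian = "little")
  invisible(path)
}

read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("read_volume: not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  type <- fields[["type"]]
  type <- c("unsigned char" = "uchar", "uchar" = "uchar", "uint8" = "uchar",
            "unsigned short" = "ushort", "ushort" = "ushort", "uint16" = "ushort",
            "int" = "int", "signed int" = "int", "int32" = "int",
            "double" = "double", "float" = "float")[[type]]
  if (is.null(type)) stop("read_volume: unsupported NRRD type")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3) stop("read_volume: only 3D NRRD supported")
  spacing <- NULL
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  if (!identical(fields[["encoding"]], "raw"))
    stop("read_volume: only raw-encoded NRRD supported")
  endian <- if (is.null(fields[["endian"]])) "little" else fields[["endian"]]
  n <- prod(sizes)
  v <- switch(type,
    uchar = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE,
                               endian = endian)),
    ushort = as.integer(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = endian)),
    int = readBin(con, "integer", n, size = 4, endian = endian),
    float = readBin(con, "double", n, size = 4, endian = endian),
    double = readBin(con, "double", n, size = 8, endian = endian))
  if (length(v) != n) stop("read_volume: truncated NRRD data")
  list(data = array(v, dim = sizes), spacing = spacing)
}

#' Interpret a volume as a binary mask
#'
#' Accepts logical data or numeric coding with values in \{0,1\} or \{0,255\}.
#' @param volume a [volume3d()].
#' @return the same volume with logical data.
#' @export
as_mask <- function(volume) {
  stopifnot(is_volume3d(volume))
  if (is.logical(volume$data)) return(volume)
  u <- unique(as.vector(volume$data))
  if (!all(u %in% c(0, 1)) && !all(u %in% c(0, 255)))
    stop("as_mask: values are not a 0/1 or 0/255 coding")
  volume$data <- array(volume$data > 0, dim = dim(volume$data))
  volume
}
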