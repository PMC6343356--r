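## Volume readers/writers.
##
## NIfTI-1: minimal single-file .nii support (uncompressed, little-endian,
## datatypes uint8 / int16 / int32 / float32 / float64), enough for lossless
## round-trips of HU volumes and masks. DICOM series are not supported in
## this build (no DICOM codec available); the loader says so explicitly.
## Raster stacks are a plain-text interchange format: a directory with a
## `meta.json` header and one whitespace-separated matrix file per slice.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32),
  `16` = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32),
  `64` = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64))

pad_chr <- function(s, n) {
  r <- charToRaw(substr(s, 1, n - 1))
  c(r, raw(n - length(r)))
}

#' Write a volume or mask as NIfTI-1
#'
#' Single-file uncompressed `.nii`, little-endian. HU volumes are stored as
#' int16 (lossless for the CT range), masks as uint8. The patient id is kept
#' in the header `descrip` field.
#'
#' @param x a [ct_volume] or a 3-D logical mask array.
#' @param path output path (`.nii`).
#' @param spacing required when `x` is a bare mask array: `c(dz, dy, dx)` mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = NULL) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels; spacing <- x$spacing; desc <- x$patient_id
    datatype <- 4L
  } else {
    check_mask(x)
    if (is.null(spacing)) stop("spacing required when writing a bare mask")
    arr <- x; desc <- "mask"; datatype <- 2L
  }
  d <- dim(arr)                      # (row, col, slice)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")
  writeBin(raw(36), con)                                  # unused header pad
  writeBin(as.integer(c(3, d[2], d[1], d[3], 1, 1, 1, 1)), con,
           size = 2, endian = "little")                   # dim[8]: x=col,y=row,z=slice
  writeBin(numeric(3), con, size = 4, endian = "little")  # intent_p1..3
  writeBin(0L, con, size = 2, endian = "little")          # intent_code
  writeBin(as.integer(c(datatype, dt$bitpix, 0)), con, size = 2, endian = "little")
  writeBin(c(1, spacing[3], spacing[2], spacing[1], 1, 1, 1, 1), con,
           size = 4, endian = "little")                   # pixdim
  writeBin(352, con, size = 4, endian = "little")         # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")     # scl_slope, scl_inter
  writeBin(0L, con, size = 2, endian = "little")          # slice_end
  writeBin(as.raw(c(0, 2)), con)                          # slice_code, xyzt_units (mm)
  writeBin(numeric(4), con, size = 4, endian = "little")  # cal_max..toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")   # glmax, glmin
  writeBin(pad_chr(desc, 80), con)                        # descrip
  writeBin(raw(24), con)                                  # aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")   # qform, sform
  writeBin(numeric(6), con, size = 4, endian = "little")  # quatern/qoffset
  writeBin(c(spacing[3], 0, 0, 0,  0, spacing[2], 0, 0,  0, 0, spacing[1], 0),
           con, size = 4, endian = "little")              # srow
  writeBin(raw(16), con)                                  # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)           # magic
  writeBin(raw(4), con)                                   # no extensions
  data <- as.vector(aperm(arr, c(2, 1, 3)))               # x fastest
  if (dt$what == "integer")
    writeBin(as.integer(data), con, size = dt$size, endian = "little")
  else
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` file written by [write_nifti()] or any uncompressed
#'   3-D NIfTI-1 file with a supported datatype.
#' @param as_mask return a logical array instead of a [ct_volume].
#' @return a [ct_volume] (or logical array when `as_mask`).
#' @export
read_nifti <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  readBin(con, "raw", 36)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  if (dims[1] != 3) stop("only 3-D NIfTI volumes are supported")
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  readBin(con, "raw", 14)                                  # intent fields
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "raw", 4)                                   # bitpix, slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl <- readBin(con, "double", 2, size = 4, endian = endian)
  readBin(con, "raw", 28)                                  # slice_end..glmin
  descrip <- readBin(con, "raw", 80)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype)
  spacing <- c(pixdim[4], pixdim[3], pixdim[2])            # (dz, dy, dx)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI pixdim has non-positive voxel spacing; refusing to default")
  seek(con, vox_offset)
  n <- as.double(nx) * ny * nz
  data <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(data) != n) stop("truncated NIfTI data section")
  if (!identical(scl, c(0, 0)) && !identical(scl, c(1, 0)) && scl[1] != 0)
    data <- data * scl[1] + scl[2]
  arr <- aperm(array(data, dim = c(nx, ny, nz)), c(2, 1, 3))
  if (as_mask) return(array(arr != 0, dim = dim(arr)))
  pid <- rawToChar(descrip[seq_len(max(0, which(descrip != 0)))])
  ct_volume(arr, spacing = spacing,
            patient_id = if (nzchar(pid)) pid else "unknown")
}

#' Write a volume as a plain-text raster stack
#'
#' Creates a directory with a `meta.json` header (patient id, spacing, shape,
#' axial positions, slice file list) and one whitespace-separated integer
#' matrix file per slice. Entirely text, diff-able, lossless.
#'
#' @param volume a [ct_volume].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_raster_stack <- function(volume, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  files <- sprintf("slice_%04d.txt", seq_len(d[3]))
  meta <- list(format = "lungcand-raster-stack", version = 1L,
               patient_id = volume$patient_id,
               spacing = volume$spacing,
               shape = c(d[3], d[1], d[2]),
               slice_z = volume$slice_z,
               slice_files = files)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_len(d[3])) {
    m <- volume$voxels[, , k]
    lines <- apply(m, 1, function(r) paste(as.integer(r), collapse = " "))
    writeLines(lines, file.path(path, files[k]))
  }
  invisible(path)
}

read_raster_stack <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("raster stack missing meta.json: ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$spacing) || any(meta$spacing <= 0))
    stop("raster stack meta.json missing voxel spacing; refusing to default")
  shp <- as.integer(meta$shape)                       # (slices, rows, cols)
  ## slices are identified by axial position, not listing order
  ord <- order(meta$slice_z)
  arr <- array(0L, dim = c(shp[2], shp[3], shp[1]))
  for (k in seq_len(shp[1])) {
    v <- scan(file.path(path, meta$slice_files[ord[k]]), what = integer(),
              quiet = TRUE)
    if (length(v) != shp[2] * shp[3])
      stop("slice ", meta$slice_files[ord[k]], " has wrong size")
    arr[, , k] <- matrix(v, nrow = shp[2], ncol = shp[3], byrow = TRUE)
  }
  ct_volume(arr, spacing = meta$spacing, patient_id = meta$patient_id,
            slice_z = sort(meta$slice_z))
}

#' Load a CT volume
#'
#' @param path file (`.nii`) or raster-stack directory.
#' @param format one of `"auto"`, `"nifti"`, `"raster-stack"`,
#'   `"dicom-series"`. DICOM is not supported in this build and errors with
#'   an explicit message rather than guessing.
#' @return a [ct_volume] with slices sorted by ascending axial position and
#'   values in HU.
#' @export
load_ct_volume <- function(path, format = c("auto", "nifti", "raster-stack",
                                            "dicom-series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "raster-stack"
              else if (grepl("\\.nii$", path)) "nifti"
              else stop("cannot infer format of ", path,
                        "; pass format= explicitly")
  }
  switch(format,
    "nifti" = read_nifti(path),
    "raster-stack" = read_raster_stack(path),
    "dicom-series" = stop(
      "DICOM series loading is not available in this build (no DICOM codec ",
      "in the dependency set). Convert the series to NIfTI or a raster ",
      "stack; HU rescale semantics are available via apply_hu_rescale()."))
}

#' Write a CT volume
#'
#' @param volume a [ct_volume].
#' @param path destination (`.nii` file or raster-stack directory).
#' @param format `"nifti"` or `"raster-stack"`; inferred from `path` when
#'   `"auto"`.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path,
                            format = c("auto", "nifti", "raster-stack")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nii$", path)) "nifti" else "raster-stack"
  if (format == "nifti") write_nifti(volume, path)
  else write_raster_stack(volume, path)
}
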