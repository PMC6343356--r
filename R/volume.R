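#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of CT attenuation in Hounsfield units (HU)
#' together with its voxel spacing. Voxels are stored as an integer-valued
#' array indexed `[row, col, slice]`; user-facing coordinates are always
#' 1-based `(slice, row, col)` triples. Axial slice positions increase with
#' slice index.
#'
#' @param voxels 3-D numeric array `[row, col, slice]` of HU values in
#'   `[-1024, 3071]`; at least 3 slices (tri-slice composites need both
#'   neighbours).
#' @param spacing numeric length-3 vector `c(dz, dy, dx)` in mm, all `> 0`.
#' @param patient_id opaque identifier string.
#' @param slice_z optional axial positions (mm), strictly increasing; default
#'   `(0:(n-1)) * dz`.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, patient_id = "anonymous",
                      slice_z = NULL) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array [row, col, slice]")
  if (dim(voxels)[3] < 3L)
    stop("a ct_volume needs at least 3 slices")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers c(dz, dy, dx) in mm")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop("HU values outside [-1024, 3071]; apply the vendor rescale first")
  if (is.null(slice_z)) slice_z <- (seq_len(dim(voxels)[3]) - 1) * spacing[1]
  if (length(slice_z) != dim(voxels)[3] || is.unsorted(slice_z, strictly = TRUE))
    stop("slice_z must be strictly increasing, one value per slice")
  structure(
    list(voxels = voxels, spacing = spacing,
         patient_id = as.character(patient_id), slice_z = as.numeric(slice_z)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s: %d slices of %d x %d, spacing (dz, dy, dx) = (%g, %g, %g) mm, HU range [%d, %d]\n",
              x$patient_id, d[3], d[1], d[2],
              x$spacing[1], x$spacing[2], x$spacing[3],
              as.integer(min(x$voxels)), as.integer(max(x$voxels))))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

n_slices <- function(volume) dim(volume$voxels)[3]

# shape as (slices, rows, cols), the order used throughout the interfaces
vol_shape <- function(volume) {
  d <- dim(volume$voxels)
  c(d[3], d[1], d[2])
}

check_mask <- function(mask, volume = NULL) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D logical array")
  if (!is.null(volume) && !identical(dim(mask), dim(volume$voxels)))
    stop("mask shape does not match volume shape")
  invisible(mask)
}

#' Apply the vendor HU rescale
#'
#' DICOM pixel data is stored as raw values; attenuation in HU is
#' `stored * slope + intercept`. Missing rescale tags must be treated as an
#' error by callers, never as an assumed identity.
#'
#' @param stored numeric array of stored pixel values.
#' @param slope,intercept rescale slope and intercept; both required.
#' @return array of HU values.
#' @export
apply_hu_rescale <- function(stored, slope, intercept) {
  if (is.null(slope) || is.null(intercept) ||
      is.na(slope) || is.na(intercept))
    stop("rescale slope/intercept missing; refusing to assume identity")
  stored * slope + intercept
}
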