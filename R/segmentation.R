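## Pulmonary parenchyma extraction.
##
## The stage sequence mirrors the classical morphological recipe:
## binarization of air-like voxels, removal of external (border-connected)
## air and extraction of the largest interior components per slice, airway /
## vessel hole filling, contour corrosion to detach pleural adhesions,
## contour mending and expansion, and finally masking the volume so only the
## parenchyma remains. All morphology is 2-D per slice.

#' Segmentation parameters
#'
#' @param hu_threshold binarization threshold (HU); voxels strictly below it
#'   count as air-like. The default -320 separates aerated lung from soft
#'   tissue; the source material never states its value, so it is exposed
#'   here.
#' @param erosion_radius_mm contour corrosion disk radius (mm).
#' @param mending_radius_mm contour mending (morphological closing) disk
#'   radius (mm). The default 4.5 re-includes juxtapleural indentations of
#'   nodules up to ~9 mm; a closing disk smaller than the nodule radius
#'   cannot fill its pleural notch.
#' @param border_margin_px air components within this many pixels of the
#'   slice border are treated as external air.
#' @param connectivity 4 or 8 (per-slice component connectivity).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(hu_threshold = -320, erosion_radius_mm = 1.5,
                                mending_radius_mm = 4.5, border_margin_px = 2,
                                connectivity = 8) {
  if (hu_threshold < -1024 || hu_threshold > 0)
    stop("hu_threshold must be in [-1024, 0]")
  if (erosion_radius_mm < 0 || mending_radius_mm < 0)
    stop("morphology radii must be >= 0")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(hu_threshold = hu_threshold,
                 erosion_radius_mm = erosion_radius_mm,
                 mending_radius_mm = mending_radius_mm,
                 border_margin_px = as.integer(border_margin_px),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Threshold binarization of a CT volume
#'
#' @param volume a [ct_volume].
#' @param hu_threshold voxels with HU strictly below this are marked
#'   (air-like = `TRUE`).
#' @return logical mask array.
#' @export
binarize <- function(volume, hu_threshold = -320) {
  array(volume$voxels < hu_threshold, dim = dim(volume$voxels))
}

#' Extract the lung field from an air mask
#'
#' Per slice: air components touching the image border (within
#' `border_margin_px`) are external air and removed; of the remaining
#' interior components, the largest is kept together with every component of
#' at least 25% of its area, so both lungs survive whether or not they are
#' connected. Slices in the middle third of the stack with no interior air
#' trigger a warning (apical/basal slices legitimately have none).
#'
#' @param air_mask mask from [binarize()].
#' @param params [segmentation_params()].
#' @param comparable_fraction keep components at least this fraction of the
#'   largest interior component's area (default 0.25).
#' @return logical mask of the lung field.
#' @export
extract_lung_mask <- function(air_mask, params = segmentation_params(),
                              comparable_fraction = 0.25) {
  check_mask(air_mask)
  d <- dim(air_mask)
  m <- params$border_margin_px
  out <- array(FALSE, dim = d)
  empty_mid <- 0L
  mid <- seq(from = ceiling(d[3] / 3), to = floor(2 * d[3] / 3))
  for (k in seq_len(d[3])) {
    lab <- .cc_label_2d(air_mask[, , k], params$connectivity)
    if (max(lab) == 0L) {
      if (k %in% mid) empty_mid <- empty_mid + 1L
      next
    }
    border_rows <- c(seq_len(m + 1L), seq(d[1] - m, d[1]))
    border_cols <- c(seq_len(m + 1L), seq(d[2] - m, d[2]))
    border_labs <- unique(c(lab[border_rows, ], lab[, border_cols]))
    areas <- tabulate(lab, nbins = max(lab))
    areas[setdiff(border_labs, 0L)] <- 0L
    if (all(areas == 0L)) {
      if (k %in% mid) empty_mid <- empty_mid + 1L
      next
    }
    keep <- which(areas >= comparable_fraction * max(areas) & areas > 0L)
    out[, , k] <- matrix(lab %in% keep, d[1], d[2])
  }
  if (empty_mid > 0L)
    warning(empty_mid, " mid-stack slice(s) without an interior air ",
            "component; left empty")
  out
}

#' Fill airway and vessel holes in a lung mask
#'
#' Per-slice hole filling: background regions not connected to the slice
#' border become foreground. Idempotent.
#'
#' @param mask lung mask.
#' @return filled mask (a superset of the input).
#' @export
fill_airways <- function(mask) {
  check_mask(mask)
  slice_apply(mask, .fill_holes_2d)
}

#' Contour mending, corrosion and expansion
#'
#' Morphological closing with a disk of `mending_radius_mm` mends the lung
#' contour, re-including juxtapleural indentations while the thin pleural
#' "lips" that frame them are still present; then erosion by a disk of
#' `erosion_radius_mm` corrodes the contour, detaching and deleting thin
#' pleural adhesions, and dilation by the same disk expands it back.
#' Mending must precede corrosion: erosion destroys the 1-2 px lips around
#' a juxtapleural bay, after which no closing of sensible radius can
#' recover the nodule. The result is a superset of the eroded mask. Slices
#' eroded to empty stay empty, with a warning.
#'
#' @param mask filled lung mask.
#' @param erosion_radius_mm,mending_radius_mm disk radii (mm). The mending
#'   disk must have at least the radius of the juxtapleural nodules that
#'   are to be recovered (default 4.5 covers nodules up to ~9 mm), and at
#'   most half the inter-lung gap so the two lungs are not bridged.
#' @param spacing voxel spacing `c(dz, dy, dx)` mm.
#' @return refined mask.
#' @export
refine_contour <- function(mask, erosion_radius_mm = 1.5,
                           mending_radius_mm = 4.5, spacing) {
  check_mask(mask)
  sp <- spacing[2:3]
  er <- disk_offsets(erosion_radius_mm, sp)
  me <- disk_offsets(mending_radius_mm, sp)
  mended <- if (mending_radius_mm > 0) mask_close(mask, me) else mask
  eroded <- if (erosion_radius_mm > 0) mask_erode(mended, er) else mended
  had <- apply(mended, 3, any)
  lost <- had & !apply(eroded, 3, any)
  if (any(lost))
    warning(sum(lost), " slice(s) eroded to empty by the corrosion radius")
  if (erosion_radius_mm > 0) mask_dilate(eroded, er) else eroded
}

#' Mask a volume down to the parenchyma
#'
#' @param volume a [ct_volume].
#' @param mask lung mask (same shape).
#' @param background_hu value written outside the mask (default -1024).
#' @return a [ct_volume] equal to `volume` inside the mask and
#'   `background_hu` elsewhere.
#' @export
apply_parenchyma_mask <- function(volume, mask, background_hu = -1024) {
  check_mask(mask, volume)
  vox <- volume$voxels
  vox[!mask] <- as.integer(background_hu)
  ct_volume(vox, spacing = volume$spacing, patient_id = volume$patient_id,
            slice_z = volume$slice_z)
}

#' Full parenchyma segmentation
#'
#' Composition binarize -> extract_lung_mask -> fill_airways ->
#' refine_contour -> apply_parenchyma_mask.
#'
#' @param volume a [ct_volume].
#' @param params [segmentation_params()].
#' @return `list(mask = <logical array>, parenchyma = <ct_volume>)`.
#' @export
segment_lungs <- function(volume, params = segmentation_params()) {
  air <- binarize(volume, params$hu_threshold)
  lungs <- extract_lung_mask(air, params)
  filled <- fill_airways(lungs)
  refined <- refine_contour(filled, params$erosion_radius_mm,
                            params$mending_radius_mm, volume$spacing)
  list(mask = refined,
       parenchyma = apply_parenchyma_mask(volume, refined))
}
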