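## Slice-wise binary morphology on 3-D masks. All structuring elements are
## disks specified in mm and converted to pixel offsets via the in-plane
## spacing, so behaviour is resolution independent.

#' Disk structuring element offsets
#'
#' @param radius_mm disk radius in mm; 0 gives the identity element.
#' @param spacing_yx in-plane spacing `c(dy, dx)` mm.
#' @return integer matrix of `(dr, dc)` offsets.
#' @keywords internal
disk_offsets <- function(radius_mm, spacing_yx) {
  if (radius_mm <= 0) return(matrix(0L, nrow = 1, ncol = 2))
  mr <- floor(radius_mm / spacing_yx[1])
  mc <- floor(radius_mm / spacing_yx[2])
  off <- expand.grid(dr = -mr:mr, dc = -mc:mc)
  keep <- (off$dr * spacing_yx[1])^2 + (off$dc * spacing_yx[2])^2 <=
    radius_mm^2
  as.matrix(off[keep, , drop = FALSE])
}

slice_apply <- function(mask, fun) {
  out <- mask
  for (k in seq_len(dim(mask)[3])) out[, , k] <- fun(mask[, , k])
  out
}

mask_erode <- function(mask, offsets)
  slice_apply(mask, function(m) .morph_2d(m, offsets, TRUE))

mask_dilate <- function(mask, offsets)
  slice_apply(mask, function(m) .morph_2d(m, offsets, FALSE))

mask_close <- function(mask, offsets)
  mask_erode(mask_dilate(mask, offsets), offsets)

mask_open <- function(mask, offsets)
  mask_dilate(mask_erode(mask, offsets), offsets)
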