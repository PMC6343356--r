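## Candidate nodule detection.
##
## Inside the parenchyma, per-slice thresholding yields bright components;
## small specks and thin elongated (vessel-like) components are deleted and
## each survivor contributes one candidate at its centroid, from which a
## 64 x 64 tri-slice ROI stack is cut. No 3-D merging happens here;
## cross-slice deduplication is an explicit later step (see
## [merge_detections()]).

#' Candidate detection parameters
#'
#' @param candidate_hu_min minimum HU of candidate tissue (default -750,
#'   low enough to catch ground-glass attenuation, which sits below that of
#'   blood vessels).
#' @param min_area_px minimum component area in pixels (inclusive).
#' @param max_axis_ratio maximum moment-ellipse major/minor axis ratio;
#'   components more elongated than this are deleted as vessel-like.
#' @param pleural_margin_mm the lung mask is eroded by this margin before
#'   the candidate search, excluding the pleural transition zone: the
#'   partial-volume band along the lung wall otherwise yields ring-shaped
#'   pseudo-candidates and contaminates juxtapleural ROIs. 0 disables.
#' @param roi_size ROI side length; fixed at 64.
#' @return object of class `candidate_params`.
#' @export
candidate_params <- function(candidate_hu_min = -750, min_area_px = 9,
                             max_axis_ratio = 3.0, pleural_margin_mm = 1.5,
                             roi_size = 64L) {
  if (roi_size != 64L) stop("roi_size is fixed at 64")
  if (min_area_px < 1) stop("min_area_px must be >= 1")
  if (max_axis_ratio < 1) stop("max_axis_ratio must be >= 1")
  if (pleural_margin_mm < 0) stop("pleural_margin_mm must be >= 0")
  structure(list(candidate_hu_min = candidate_hu_min,
                 min_area_px = as.integer(min_area_px),
                 max_axis_ratio = max_axis_ratio,
                 pleural_margin_mm = pleural_margin_mm, roi_size = 64L),
            class = "candidate_params")
}

#' Convert an area in mm^2 to pixels
#' @param area_mm2 area in mm^2.
#' @param spacing voxel spacing `c(dz, dy, dx)` mm.
#' @return area in pixels (in-plane).
#' @export
area_mm2_to_px <- function(area_mm2, spacing) {
  area_mm2 / (spacing[2] * spacing[3])
}

## moment-ellipse axis lengths from pixel coordinates (rows, cols);
## convention: 4 * sqrt(eigenvalue of the coordinate covariance), with
## major = minor = 1 for single pixels and minor = 0 (ratio Inf) for
## collinear multi-pixel components.
component_axes <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) return(c(major = 1, minor = 1))
  mu20 <- mean((cols - mean(cols))^2)
  mu02 <- mean((rows - mean(rows))^2)
  mu11 <- mean((rows - mean(rows)) * (cols - mean(cols)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(0, tr / 2 - disc)
  c(major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

#' Label candidate components on every slice
#'
#' Pixels inside the lung mask with HU at or above `candidate_hu_min` are
#' labelled into 8-connected per-slice components; each component carries
#' its area, centroid and moment-ellipse axes.
#'
#' @param parenchyma parenchyma [ct_volume] (background already blanked).
#' @param mask lung mask aligned with `parenchyma`.
#' @param candidate_hu_min threshold (HU).
#' @param connectivity 4 or 8.
#' @return data.frame with one row per component: `slice`, `label`,
#'   `area_px`, `row`, `col` (centroid, fractional), `major`, `minor`,
#'   `axis_ratio`.
#' @export
label_candidate_components <- function(parenchyma, mask,
                                       candidate_hu_min = -750,
                                       connectivity = 8) {
  check_mask(mask, parenchyma)
  d <- dim(parenchyma$voxels)
  rows <- list()
  for (k in seq_len(d[3])) {
    fg <- mask[, , k] & parenchyma$voxels[, , k] >= candidate_hu_min
    if (!any(fg)) next
    lab <- .cc_label_2d(fg, connectivity)
    idx <- which(lab > 0L)
    comp <- lab[idx]
    rc <- arrayInd(idx, .dim = d[1:2])
    for (l in seq_len(max(lab))) {
      sel <- comp == l
      r <- rc[sel, 1]; c <- rc[sel, 2]
      ax <- component_axes(r, c)
      ratio <- if (ax["minor"] > 0) ax["major"] / ax["minor"] else Inf
      rows[[length(rows) + 1L]] <- data.frame(
        slice = k, label = l, area_px = sum(sel),
        row = mean(r), col = mean(c),
        major = unname(ax["major"]), minor = unname(ax["minor"]),
        axis_ratio = unname(ratio))
    }
  }
  if (length(rows) == 0)
    return(data.frame(slice = integer(0), label = integer(0),
                      area_px = integer(0), row = numeric(0),
                      col = numeric(0), major = numeric(0),
                      minor = numeric(0), axis_ratio = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delete small components
#'
#' Keeps components with `area_px >= min_area_px` (inclusive boundary).
#'
#' @param components component table from [label_candidate_components()].
#' @param min_area_px minimum area in pixels.
#' @return filtered component table.
#' @export
filter_small_components <- function(components, min_area_px = 9) {
  components[components$area_px >= min_area_px, , drop = FALSE]
}

#' Delete thin, elongated components
#'
#' Removes components whose moment-ellipse major/minor axis ratio exceeds
#' `max_axis_ratio`; degenerate (collinear) components count as infinitely
#' elongated and are removed.
#'
#' @param components component table.
#' @param max_axis_ratio ratio threshold.
#' @return filtered component table.
#' @export
filter_elongated_components <- function(components, max_axis_ratio = 3.0) {
  components[components$axis_ratio <= max_axis_ratio, , drop = FALSE]
}

#' Candidate-search view of a parenchyma volume
#'
#' Applies the pleural margin of `params`: the mask is eroded by
#' `pleural_margin_mm` and the volume blanked outside it. This is the exact
#' volume [detect_candidates()] searches and cuts ROIs from; use it when
#' scoring ROIs at known locations so they match pipeline ROIs.
#'
#' @param volume parenchyma [ct_volume].
#' @param mask lung mask.
#' @param params [candidate_params()].
#' @return `list(volume, mask)` with the margin applied.
#' @export
detection_volume <- function(volume, mask, params = candidate_params()) {
  if (params$pleural_margin_mm > 0) {
    mask <- mask_erode(mask, disk_offsets(params$pleural_margin_mm,
                                          volume$spacing[2:3]))
    volume <- apply_parenchyma_mask(volume, mask)
  }
  list(volume = volume, mask = mask)
}

#' Cut a 64 x 64 tri-slice ROI stack
#'
#' Crops `roi_size` x `roi_size` windows centred at `(row, col)` (centroid
#' pixel at patch position 33, i.e. 0-based index 32) from slices
#' `z - 1, z, z + 1`. Windows overhanging the image edge are padded with
#' background (-1024 HU); at the first/last slice the missing neighbour is
#' replicated from the centre slice.
#'
#' @param volume a [ct_volume] (at least 3 slices).
#' @param center `(slice, row, col)` 1-based voxel coordinates.
#' @param roi_size side length (64).
#' @param provenance character record of the filters the candidate
#'   survived.
#' @return object of class `candidate_roi`: list with `patient_id`,
#'   `center`, `stack` (`roi_size` x `roi_size` x 3 array, third index =
#'   slice z-1, z, z+1), `provenance`, `truth` (NA until labelled).
#' @export
extract_roi_stack <- function(volume, center, roi_size = 64L,
                              provenance = character(0)) {
  d <- dim(volume$voxels)
  if (d[3] < 3L) stop("volume must have at least 3 slices")
  z <- center[1]; r0 <- center[2]; c0 <- center[3]
  if (z < 1 || z > d[3] || r0 < 1 || r0 > d[1] || c0 < 1 || c0 > d[2])
    stop("ROI center outside volume bounds")
  half <- roi_size %/% 2L
  rows <- (r0 - half):(r0 + half - 1L)
  cols <- (c0 - half):(c0 + half - 1L)
  crop <- function(k) {
    patch <- matrix(-1024L, roi_size, roi_size)
    rin <- rows >= 1 & rows <= d[1]
    cin <- cols >= 1 & cols <= d[2]
    patch[rin, cin] <- volume$voxels[rows[rin], cols[cin], k]
    patch
  }
  zs <- clamp(c(z - 1L, z, z + 1L), 1L, d[3])
  stack <- array(0L, dim = c(roi_size, roi_size, 3L))
  for (i in 1:3) stack[, , i] <- crop(zs[i])
  structure(list(patient_id = volume$patient_id,
                 center = c(slice = z, row = r0, col = c0),
                 stack = stack, provenance = provenance,
                 truth = NA),
            class = "candidate_roi")
}

#' Detect candidate nodules
#'
#' Composition: shave the pleural margin off the mask -> label components
#' -> delete small -> delete elongated -> take centroids -> cut tri-slice
#' ROI stacks (from the margin-masked parenchyma, so ROIs carry no
#' pleural-band pixels). Candidates are ordered by (slice, row, col), so
#' repeated runs are identical.
#'
#' @param volume parenchyma [ct_volume].
#' @param mask lung mask.
#' @param params [candidate_params()].
#' @return list of [extract_roi_stack()] candidates; the component table is
#'   attached as attribute `components`.
#' @export
detect_candidates <- function(volume, mask, params = candidate_params()) {
  dv <- detection_volume(volume, mask, params)
  volume <- dv$volume; mask <- dv$mask
  comp <- label_candidate_components(volume, mask, params$candidate_hu_min)
  comp <- filter_small_components(comp, params$min_area_px)
  comp <- filter_elongated_components(comp, params$max_axis_ratio)
  comp <- comp[order(comp$slice, comp$row, comp$col), , drop = FALSE]
  cands <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    center <- c(comp$slice[i], round(comp$row[i]), round(comp$col[i]))
    cands[[i]] <- extract_roi_stack(
      volume, center, params$roi_size,
      provenance = c("threshold", "small-structure", "thin-long-structure"))
  }
  attr(cands, "components") <- comp
  cands
}
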