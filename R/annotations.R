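## Nodule annotations.
##
## Annotations are rows of a plain data.frame (one row per reader x nodule
## mark, never merged across readers): identifiers, a 1-based voxel centroid
## (slice, row, col), diameter in mm, the nine LIDC characteristic ratings,
## and a derived GGO flag. Marks without characteristics (the small-nodule /
## non-nodule dialect) are kept and flagged, not dropped.

CHARACTERISTIC_RANGES <- list(
  subtlety           = c(1L, 5L),
  internal_structure = c(1L, 4L),
  calcification      = c(1L, 6L),
  sphericity         = c(1L, 5L),
  margin             = c(1L, 5L),
  lobulation         = c(1L, 5L),
  spiculation        = c(1L, 5L),
  texture            = c(1L, 5L),
  malignancy         = c(1L, 5L))

CHARACTERISTIC_XML_NAMES <- c(
  subtlety = "subtlety", internal_structure = "internalStructure",
  calcification = "calcification", sphericity = "sphericity",
  margin = "margin", lobulation = "lobulation",
  spiculation = "spiculation", texture = "texture",
  malignancy = "malignancy")

#' Construct and validate a nodule annotation table
#'
#' @param df data.frame with columns `nodule_id`, `reader_id`, `slice`,
#'   `row`, `col`, `diameter_mm`, the nine characteristic columns (NA when
#'   the mark carries none), and logicals `has_characteristics`, `is_ggo`.
#' @param volume optional [ct_volume]; when given, centroids are checked to
#'   lie inside its bounds.
#' @return the validated data.frame.
#' @export
nodule_annotations <- function(df, volume = NULL) {
  needed <- c("nodule_id", "reader_id", "slice", "row", "col", "diameter_mm",
              names(CHARACTERISTIC_RANGES), "has_characteristics", "is_ggo")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("annotation table missing columns: ",
         paste(missing_cols, collapse = ", "))
  for (ch in names(CHARACTERISTIC_RANGES)) {
    v <- df[[ch]]
    rng <- CHARACTERISTIC_RANGES[[ch]]
    bad <- !is.na(v) & (v < rng[1] | v > rng[2] | v != round(v))
    if (any(bad))
      stop(sprintf("characteristic '%s' outside valid range [%d, %d]: %s",
                   ch, rng[1], rng[2],
                   paste(v[bad], collapse = ", ")))
  }
  if (any(!is.na(df$diameter_mm) & df$diameter_mm <= 0))
    stop("diameter_mm must be > 0 when present")
  if (!is.null(volume)) {
    d <- vol_shape(volume)
    ok <- df$slice >= 1 & df$slice <= d[1] &
      df$row >= 1 & df$row <= d[2] & df$col >= 1 & df$col <= d[3]
    if (any(!ok))
      stop("annotation centroid(s) outside volume bounds: rows ",
           paste(which(!ok), collapse = ", "))
  }
  df
}

#' Decide the GGO flag from characteristic ratings
#'
#' Ground-glass marks are selected on the texture (1 = non-solid/GGO up to
#' 5 = solid) and internal-structure (1 = soft tissue) ratings. The exact
#' cut-offs are configurable assumptions: texture `<= texture_max` and
#' internal structure `== internal_structure_value`.
#'
#' @param texture,internal_structure integer ratings (NA allowed).
#' @param texture_max inclusive texture cut-off, default 2.
#' @param internal_structure_value required internal-structure rating,
#'   default 1.
#' @return logical vector (NA where ratings are NA).
#' @export
is_ggo_rating <- function(texture, internal_structure,
                          texture_max = 2L, internal_structure_value = 1L) {
  texture <= texture_max & internal_structure == internal_structure_value
}

read_characteristics <- function(node) {
  out <- rep(NA_integer_, length(CHARACTERISTIC_RANGES))
  names(out) <- names(CHARACTERISTIC_RANGES)
  chars <- xml2::xml_find_first(node, "./characteristics")
  if (inherits(chars, "xml_missing")) return(out)
  for (ch in names(CHARACTERISTIC_XML_NAMES)) {
    v <- xml2::xml_find_first(chars, paste0("./", CHARACTERISTIC_XML_NAMES[ch]))
    if (!inherits(v, "xml_missing")) {
      val <- suppressWarnings(as.integer(xml2::xml_text(v)))
      rng <- CHARACTERISTIC_RANGES[[ch]]
      if (is.na(val) || val < rng[1] || val > rng[2])
        stop(sprintf("characteristic '%s' value '%s' outside valid range [%d, %d]",
                     ch, xml2::xml_text(v), rng[1], rng[2]))
      out[ch] <- val
    }
  }
  out
}

#' Parse LIDC-style XML nodule annotations
#'
#' One annotation per (reading session, nodule) pair; per-reader marks are
#' never merged. Pixel coordinates in the XML are 1-based and used as-is;
#' the centroid is the mean of all edge-map points of the mark. Slice
#' indices are resolved against `slice_z` (the volume's axial positions)
#' when supplied, otherwise against the sorted distinct z positions present
#' in the file.
#'
#' @param xml path to an XML file, an XML string, or an `xml2` document.
#' @param pixel_spacing_mm in-plane spacing `c(dy, dx)`; needed to express
#'   the mark's extent as a diameter in mm (otherwise the non-standard
#'   `<diameterMm>` element is honoured, else NA).
#' @param slice_z optional axial slice positions of the annotated volume.
#' @param texture_max,internal_structure_value GGO rule, see
#'   [is_ggo_rating()].
#' @return annotation data.frame (see [nodule_annotations()]).
#' @export
parse_lidc_annotations <- function(xml, pixel_spacing_mm = NULL,
                                   slice_z = NULL, texture_max = 2L,
                                   internal_structure_value = 1L) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  xml2::xml_ns_strip(doc)
  sessions <- xml2::xml_find_all(doc, ".//readingSession")
  if (length(sessions) == 0)
    stop("no readingSession elements found; not a LIDC-style file?")
  all_z <- sort(unique(as.numeric(xml2::xml_text(
    xml2::xml_find_all(doc, ".//imageZposition")))))
  z_to_slice <- function(z) {
    ref <- if (!is.null(slice_z)) slice_z else all_z
    which.min(abs(ref - z))
  }
  rows <- list()
  for (s in seq_along(sessions)) {
    reader <- xml2::xml_text(
      xml2::xml_find_first(sessions[[s]], "./servicingRadiologistID"))
    if (is.na(reader) || !nzchar(reader)) reader <- sprintf("reader%02d", s)
    for (nod in xml2::xml_find_all(sessions[[s]],
                                   "./unblindedReadNodule | ./unblindedRead")) {
      nid <- xml2::xml_text(xml2::xml_find_first(nod, "./noduleID"))
      chars <- read_characteristics(nod)
      xs <- as.numeric(xml2::xml_text(
        xml2::xml_find_all(nod, ".//edgeMap/xCoord | .//locus/xCoord")))
      ys <- as.numeric(xml2::xml_text(
        xml2::xml_find_all(nod, ".//edgeMap/yCoord | .//locus/yCoord")))
      zs <- as.numeric(xml2::xml_text(
        xml2::xml_find_all(nod, ".//roi/imageZposition")))
      if (length(xs) == 0)
        stop("nodule ", nid, " has no edge map or locus coordinates")
      dia <- NA_real_
      dia_node <- xml2::xml_find_first(nod, "./diameterMm")
      if (!inherits(dia_node, "xml_missing")) {
        dia <- as.numeric(xml2::xml_text(dia_node))
      } else if (!is.null(pixel_spacing_mm) && length(xs) > 1) {
        dx <- outer(xs, xs, "-") * pixel_spacing_mm[2]
        dy <- outer(ys, ys, "-") * pixel_spacing_mm[1]
        dia <- max(sqrt(dx^2 + dy^2))
      }
      has_chars <- !all(is.na(chars))
      rows[[length(rows) + 1L]] <- data.frame(
        nodule_id = nid, reader_id = reader,
        slice = z_to_slice(mean(zs)),
        row = round(mean(ys)), col = round(mean(xs)),
        diameter_mm = dia,
        as.list(chars),
        has_characteristics = has_chars,
        is_ggo = if (has_chars)
          is_ggo_rating(chars["texture"], chars["internal_structure"],
                        texture_max, internal_structure_value)
        else NA,
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  nodule_annotations(ann)
}

#' Serialize annotations to the LIDC-style XML dialect
#'
#' Writes one reading session per reader and a degenerate single-point edge
#' map at the centroid, plus a non-standard `<diameterMm>` element so that
#' parse -> serialize -> parse is idempotent.
#'
#' @param annotations annotation data.frame.
#' @param path output path.
#' @param slice_z axial positions used to express slice indices as
#'   `imageZposition` values; default `slice - 1` (unit spacing).
#' @return `path`, invisibly.
#' @export
write_lidc_xml <- function(annotations, path, slice_z = NULL) {
  if (is.null(slice_z)) slice_z <- seq_len(max(annotations$slice)) - 1
  doc <- xml2::xml_new_root("LidcReadMessage")
  for (reader in unique(annotations$reader_id)) {
    ses <- xml2::xml_add_child(doc, "readingSession")
    xml2::xml_add_child(ses, "servicingRadiologistID", reader)
    sub <- annotations[annotations$reader_id == reader, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      nod <- xml2::xml_add_child(ses, "unblindedReadNodule")
      xml2::xml_add_child(nod, "noduleID", sub$nodule_id[i])
      if (sub$has_characteristics[i]) {
        chars <- xml2::xml_add_child(nod, "characteristics")
        for (ch in names(CHARACTERISTIC_XML_NAMES))
          xml2::xml_add_child(chars, CHARACTERISTIC_XML_NAMES[[ch]],
                              as.character(sub[[ch]][i]))
      }
      if (!is.na(sub$diameter_mm[i]))
        xml2::xml_add_child(nod, "diameterMm",
                            format(sub$diameter_mm[i], digits = 10))
      roi <- xml2::xml_add_child(nod, "roi")
      xml2::xml_add_child(roi, "imageZposition",
                          format(slice_z[sub$slice[i]], digits = 10))
      xml2::xml_add_child(roi, "inclusion", "TRUE")
      edge <- xml2::xml_add_child(roi, "edgeMap")
      xml2::xml_add_child(edge, "xCoord", as.character(sub$col[i]))
      xml2::xml_add_child(edge, "yCoord", as.character(sub$row[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Select GGO annotations by internal structure and texture
#'
#' Returns exactly the annotations with `texture <= texture_max` and
#' `internal_structure == internal_structure_value`, in input order.
#' Annotations without characteristics are excluded with a warning.
#'
#' @param annotations annotation data.frame.
#' @param texture_max inclusive texture cut-off (default 2: non-solid and
#'   part-solid ratings).
#' @param internal_structure_value required internal-structure rating
#'   (default 1, soft tissue).
#' @return subset of `annotations`.
#' @export
select_ggo_annotations <- function(annotations, texture_max = 2L,
                                   internal_structure_value = 1L) {
  no_chars <- !annotations$has_characteristics
  if (any(no_chars))
    warning(sum(no_chars),
            " annotation(s) without characteristics excluded from GGO selection")
  keep <- annotations$has_characteristics &
    !is.na(annotations$texture) &
    annotations$texture <= texture_max &
    annotations$internal_structure == internal_structure_value
  annotations[keep, , drop = FALSE]
}

#' Union-of-readers view of an annotation table
#'
#' Greedily clusters marks whose centroids lie within `merge_distance_mm`
#' of each other (3-D physical distance) and keeps one row per cluster: the
#' mean centroid, the maximum diameter and the first reader's ratings, with
#' a `n_readers` column. A convenience view for evaluation only; the
#' per-reader table remains the primary representation.
#'
#' @param annotations annotation data.frame.
#' @param spacing voxel spacing `c(dz, dy, dx)` mm.
#' @param merge_distance_mm cluster radius, default 5.
#' @return merged annotation data.frame with `n_readers`.
#' @export
union_reader_annotations <- function(annotations, spacing,
                                     merge_distance_mm = 5) {
  if (nrow(annotations) == 0)
    return(cbind(annotations, n_readers = integer(0)))
  pos <- cbind(annotations$slice * spacing[1],
               annotations$row * spacing[2],
               annotations$col * spacing[3])
  cluster <- rep(NA_integer_, nrow(annotations))
  k <- 0L
  for (i in seq_len(nrow(annotations))) {
    if (!is.na(cluster[i])) next
    k <- k + 1L
    d <- sqrt(rowSums((pos - matrix(pos[i, ], nrow(pos), 3, byrow = TRUE))^2))
    cluster[is.na(cluster) & d <= merge_distance_mm] <- k
  }
  merged <- lapply(split(seq_len(nrow(annotations)), cluster), function(idx) {
    first <- annotations[idx[1], , drop = FALSE]
    first$slice <- round(mean(annotations$slice[idx]))
    first$row <- round(mean(annotations$row[idx]))
    first$col <- round(mean(annotations$col[idx]))
    dm <- annotations$diameter_mm[idx]
    first$diameter_mm <- if (all(is.na(dm))) NA_real_ else max(dm, na.rm = TRUE)
    first$n_readers <- length(unique(annotations$reader_id[idx]))
    first
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Write an annotation table as CSV
#' @param annotations annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
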