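## End-to-end orchestration: segment -> detect -> encode -> score ->
## (merge) -> evaluate. A pipeline run is fully described by its config and
## seed; regenerating from the same config yields an identical report
## object.

#' Pipeline configuration
#'
#' @param input either `list(type = "phantom", preset = <difficulty>,
#'   noise_sd = <HU>)` or `list(type = "volume", path = <file>, annotations
#'   = <xml path or NULL>)`.
#' @param seg [segmentation_params()].
#' @param cand [candidate_params()].
#' @param window HU window `c(center_hu, width_hu)` for the RGB encoding.
#' @param scorer registered scorer name (see [register_scorer()]).
#' @param scorer_params list of extra arguments passed to the scorer.
#' @param thresholds decision threshold grid.
#' @param nms_radius_mm non-maximum-suppression radius for cross-slice
#'   deduplication of detections (see [merge_detections()]).
#' @param output_dir optional directory; when set, the run writes its
#'   resolved config, candidate table, sweep tables and a Markdown report.
#' @param seed integer seed controlling every random element of the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "phantom", preset = "easy",
                                         noise_sd = 20),
                            seg = segmentation_params(),
                            cand = candidate_params(),
                            window = c(center_hu = -600, width_hu = 1500),
                            scorer = "baseline",
                            scorer_params = list(),
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            nms_radius_mm = 10,
                            output_dir = NULL,
                            seed = 1L) {
  if (!input$type %in% c("phantom", "volume"))
    stop("input$type must be 'phantom' or 'volume'")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  structure(list(input = input, seg = seg, cand = cand, window = window,
                 scorer = scorer, scorer_params = scorer_params,
                 thresholds = thresholds, nms_radius_mm = nms_radius_mm,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / read a pipeline config as JSON
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return reader returns a [pipeline_config()]; writer returns `path`
#'   invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  out <- strip(config)
  out$window <- as.list(config$window)   # keep the names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(input = raw$input,
                  seg = do.call(segmentation_params, raw$seg),
                  cand = do.call(candidate_params, raw$cand),
                  window = unlist(raw$window),
                  scorer = raw$scorer,
                  scorer_params = as.list(raw$scorer_params),
                  thresholds = raw$thresholds,
                  nms_radius_mm = raw$nms_radius_mm,
                  output_dir = raw$output_dir,
                  seed = raw$seed)
}

resolve_input <- function(config) {
  inp <- config$input
  if (inp$type == "phantom") {
    noise <- if (is.null(inp$noise_sd)) 20 else inp$noise_sd
    ph <- generate_phantom(default_test_spec(inp$preset, noise_sd = noise,
                                             seed = config$seed))
    list(volume = ph$volume, annotations = ph$annotations,
         truth_mask = ph$lung_mask)
  } else {
    vol <- load_ct_volume(inp$path)
    ann <- NULL
    if (!is.null(inp$annotations)) {
      ann <- if (grepl("\\.xml$", inp$annotations))
        parse_lidc_annotations(inp$annotations,
                               pixel_spacing_mm = vol$spacing[2:3],
                               slice_z = vol$slice_z)
      else read.csv(inp$annotations, stringsAsFactors = FALSE)
    }
    list(volume = vol, annotations = ann, truth_mask = NULL)
  }
}

## label candidates against truth: center inside max(radius, floor) of a
## nodule centroid
label_candidates <- function(cand_df, annotations, spacing,
                             min_match_radius_mm = 1.5) {
  if (is.null(annotations) || nrow(annotations) == 0 || nrow(cand_df) == 0)
    return(rep(FALSE, nrow(cand_df)))
  apos <- cbind(annotations$slice * spacing[1],
                annotations$row * spacing[2],
                annotations$col * spacing[3])
  lim <- pmax(annotations$diameter_mm / 2, min_match_radius_mm)
  lim[is.na(lim)] <- min_match_radius_mm
  vapply(seq_len(nrow(cand_df)), function(i) {
    p <- c(cand_df$slice[i] * spacing[1], cand_df$row[i] * spacing[2],
           cand_df$col[i] * spacing[3])
    d <- sqrt(rowSums((apos - matrix(p, nrow(apos), 3, byrow = TRUE))^2))
    any(d <= lim)
  }, logical(1))
}

#' Run the full detection pipeline
#'
#' Segments the lungs, detects candidates, encodes each as an RGB
#' composite, scores it with the configured scorer, deduplicates detections
#' across slices, and - when ground truth is available - evaluates a
#' threshold sweep at both ROI level (classification of each candidate
#' patch) and nodule level (detection matching with FP counting and average
#' FP per patient), plus a size-stratified sensitivity table at the best
#' threshold.
#'
#' @param config a [pipeline_config()].
#' @return object of class `detection_report`: `candidates` (per-candidate
#'   centres and scores), `detections` (NMS survivors), `roi_sweep`,
#'   `detection_sweep`, `size_report`, `best_threshold`,
#'   `average_fp_best`, `segmentation_dice` (phantom runs), `mask`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inp <- stage("input", resolve_input(config))
  vol <- inp$volume
  seg <- stage("segment", segment_lungs(vol, config$seg))
  cands <- stage("detect",
                 detect_candidates(seg$parenchyma, seg$mask, config$cand))
  scorer <- get_scorer(config$scorer)
  cand_df <- attr(cands, "components")
  scores <- numeric(length(cands))
  for (i in seq_along(cands)) {
    comp <- compose_rgb(cands[[i]], config$window[["center_hu"]],
                        config$window[["width_hu"]])
    scores[i] <- do.call(scorer, c(list(comp), config$scorer_params))
  }
  cand_tab <- data.frame(
    patient_id = rep(vol$patient_id, nrow(cand_df)),
    slice = cand_df$slice, row = round(cand_df$row),
    col = round(cand_df$col), area_px = cand_df$area_px,
    axis_ratio = cand_df$axis_ratio, score = scores)
  detections <- merge_detections(cand_tab, vol$spacing,
                                 config$nms_radius_mm)
  ann <- inp$annotations
  roi_sweep <- detection_sweep <- size_report <- NULL
  best_threshold <- avg_fp_best <- NA_real_
  if (!is.null(ann) && nrow(cand_tab) > 0) {
    truth <- label_candidates(cand_tab, ann, vol$spacing)
    cand_tab$truth <- truth
    roi_sweep <- threshold_sweep(cand_tab$score, truth, config$thresholds)
    det_rows <- list()
    best_key <- c(-Inf, Inf)
    best_hits <- NULL
    for (th in config$thresholds) {
      pos <- detections[classify_at_threshold(detections$score, th), ,
                        drop = FALSE]
      m <- match_detections(pos, ann, vol$spacing)
      met <- compute_metrics(m$counts, threshold = th)
      met$average_fp <- average_false_positive(m$counts$fp, 1L)
      det_rows[[length(det_rows) + 1L]] <- met
      key <- c(met$sensitivity, m$counts$fp)
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best_key <- key
        best_threshold <- th
        avg_fp_best <- met$average_fp
        best_hits <- m$hits
      }
    }
    detection_sweep <- do.call(rbind, det_rows)
    if (!is.null(best_hits) && all(!is.na(ann$diameter_mm)))
      size_report <- size_stratified_report(best_hits, ann)
  }
  seg_dice <- if (!is.null(inp$truth_mask))
    dice(seg$mask, inp$truth_mask) else NA_real_
  report <- structure(
    list(candidates = cand_tab, detections = detections,
         roi_sweep = roi_sweep, detection_sweep = detection_sweep,
         size_report = size_report, best_threshold = best_threshold,
         average_fp_best = avg_fp_best, segmentation_dice = seg_dice,
         mask = seg$mask,
         provenance = list(
           config = config, seed = config$seed,
           config_crc32 = .crc32_raw(serialize(
             rapply(config, unclass, how = "replace"), NULL, version = 2)),
           package_version = as.character(utils::packageVersion("lungcand")))),
    class = "detection_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %d candidate(s), %d after merge",
              nrow(x$candidates), nrow(x$detections)))
  if (!is.na(x$segmentation_dice))
    cat(sprintf(", segmentation Dice %.3f", x$segmentation_dice))
  cat("\n")
  if (!is.null(x$detection_sweep)) {
    best <- x$detection_sweep[x$detection_sweep$threshold == x$best_threshold, ]
    cat(sprintf("  best threshold %.1f: sensitivity %.3f, %d FP (%.1f per patient)\n",
                x$best_threshold, best$sensitivity, best$fp, x$average_fp_best))
  }
  invisible(x)
}

#' Write a detection report to a directory
#'
#' Emits the resolved config (JSON), candidate and detection tables (CSV),
#' the ROI and detection sweeps (CSV), the size-stratified table and a
#' Markdown summary. The written config re-runs to an identical report.
#'
#' @param report a `detection_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$provenance$config
  cfg$output_dir <- NULL
  write_pipeline_config(cfg, file.path(dir, "config.json"))
  write.csv(report$candidates, file.path(dir, "candidates.csv"),
            row.names = FALSE)
  write.csv(report$detections, file.path(dir, "detections.csv"),
            row.names = FALSE)
  md <- c("# Detection report", "",
          sprintf("- patient: %s", report$candidates$patient_id[1]),
          sprintf("- candidates: %d (after merge: %d)",
                  nrow(report$candidates), nrow(report$detections)),
          sprintf("- segmentation Dice: %s",
                  ifelse(is.na(report$segmentation_dice), "n/a",
                         sprintf("%.4f", report$segmentation_dice))),
          sprintf("- config crc32: %.0f", report$provenance$config_crc32),
          "")
  if (!is.null(report$roi_sweep)) {
    write.csv(report$roi_sweep, file.path(dir, "roi_sweep.csv"),
              row.names = FALSE)
    md <- c(md, "## ROI-level threshold sweep", "",
            format_table_markdown(report$roi_sweep), "")
  }
  if (!is.null(report$detection_sweep)) {
    write.csv(report$detection_sweep, file.path(dir, "detection_sweep.csv"),
              row.names = FALSE)
    md <- c(md, "## Nodule-level detection sweep", "",
            format_table_markdown(report$detection_sweep), "")
  }
  if (!is.null(report$size_report)) {
    write.csv(report$size_report, file.path(dir, "size_report.csv"),
              row.names = FALSE)
    md <- c(md, sprintf("## Sensitivity by nodule size (threshold %.1f)",
                        report$best_threshold), "",
            format_table_markdown(report$size_report, digits = 1), "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
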