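## Detection evaluation calculus.
##
## Confusion counts, the metric set (sensitivity/TPR, precision,
## specificity, false-positive rate, F-score, accuracy), detection-truth
## matching, threshold sweeps, size-stratified sensitivity and average
## false positives per patient. Undefined metrics (zero denominators) are
## NA, never 0: silently zero-filling would inflate sweeps at extreme
## thresholds.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts. `tp` = nodules
#'   identified as nodules, `fp` = normal tissue judged as nodule, `tn` =
#'   normal tissue judged normal, `fn` = missed nodules.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  v <- as.integer(v)
  structure(list(tp = v[1], fp = v[2], tn = v[3], fn = v[4]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classify a probability at a decision threshold
#'
#' Positive iff `probability > threshold` (strict: a value equal to the
#' threshold is judged normal tissue).
#'
#' @param probability,threshold values in `[0, 1]` (vectorized over
#'   `probability`).
#' @return logical vector.
#' @export
classify_at_threshold <- function(probability, threshold) {
  if (any(probability < 0 | probability > 1) || threshold < 0 || threshold > 1)
    stop("probability and threshold must lie in [0, 1]")
  probability > threshold
}

#' Tally a confusion matrix from predicted and true labels
#'
#' @param predictions,truths logical vectors of equal length.
#' @return [confusion_counts()].
#' @export
confusion_from_labels <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  confusion_counts(tp = sum(predictions & truths),
                   fp = sum(predictions & !truths),
                   tn = sum(!predictions & !truths),
                   fn = sum(!predictions & truths))
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Compute the metric set from confusion counts
#'
#' Sensitivity/TPR `= TP/(TP+FN)`, precision `= TP/(TP+FP)`, specificity
#' `= TN/(TN+FP)`, false-positive rate `= FP/(TN+FP)`,
#' `F = 2 * precision * TPR / (precision + TPR)`, accuracy
#' `= (TP+TN)/total`. Any zero denominator makes that metric NA; F is NA if
#' either input is NA, and 0 when both are defined and both are 0.
#'
#' @param counts a [confusion_counts()].
#' @param threshold optional threshold to record in the row.
#' @return one-row data.frame (a metrics row).
#' @export
compute_metrics <- function(counts, threshold = NA_real_) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  sens <- safe_ratio(tp, tp + fn)
  prec <- safe_ratio(tp, tp + fp)
  spec <- safe_ratio(tn, tn + fp)
  fpr <- safe_ratio(fp, tn + fp)
  f <- if (is.na(prec) || is.na(sens)) NA_real_
       else if (prec + sens == 0) 0
       else 2 * prec * sens / (prec + sens)
  acc <- safe_ratio(tp + tn, tp + fp + tn + fn)
  data.frame(threshold = threshold, tp = tp, fn = fn, fp = fp, tn = tn,
             sensitivity = sens, precision = prec, specificity = spec,
             false_positive_rate = fpr, f_score = f, accuracy = acc)
}

#' Average false positives per patient
#'
#' The per-patient FP burden: total false positives divided by the number
#' of patients.
#'
#' @param total_fp total false-positive count (`>= 0`).
#' @param n_patients number of patients (`>= 1`).
#' @return rate.
#' @export
average_false_positive <- function(total_fp, n_patients) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  total_fp / n_patients
}

#' Match detections to ground-truth annotations
#'
#' Greedy nearest-first matching in physical space: a detection hits an
#' annotation when the 3-D distance between detection centre and annotation
#' centroid is at most `max(diameter/2, min_match_radius_mm)`. Each
#' annotation is matched at most once; extra detections of one nodule count
#' as FP, unmatched annotations as FN. TN is not defined at detection level
#' and is reported as 0.
#'
#' @param detections data.frame with `slice`, `row`, `col` (1-based voxel
#'   coordinates).
#' @param annotations annotation data.frame with `slice`, `row`, `col`,
#'   `diameter_mm`.
#' @param spacing voxel spacing `c(dz, dy, dx)` mm (required).
#' @param min_match_radius_mm floor of the hit radius (default 1.5).
#' @return list: `counts` ([confusion_counts()]), `hits` (logical per
#'   annotation), `detection_matched` (logical per detection),
#'   `matched_annotation` (index per detection, NA if unmatched).
#' @export
match_detections <- function(detections, annotations, spacing,
                             min_match_radius_mm = 1.5) {
  if (missing(spacing) || is.null(spacing)) stop("spacing is required")
  nd <- nrow(detections); na <- nrow(annotations)
  hits <- rep(FALSE, na)
  dmatched <- rep(FALSE, nd)
  massign <- rep(NA_integer_, nd)
  if (nd > 0 && na > 0) {
    dpos <- cbind(detections$slice * spacing[1], detections$row * spacing[2],
                  detections$col * spacing[3])
    apos <- cbind(annotations$slice * spacing[1], annotations$row * spacing[2],
                  annotations$col * spacing[3])
    dist <- sqrt(outer(dpos[, 1], apos[, 1], "-")^2 +
                   outer(dpos[, 2], apos[, 2], "-")^2 +
                   outer(dpos[, 3], apos[, 3], "-")^2)
    lim <- pmax(annotations$diameter_mm / 2, min_match_radius_mm)
    lim[is.na(lim)] <- min_match_radius_mm
    maxlim <- max(lim)
    for (k in order(dist)) {
      ij <- arrayInd(k, dim(dist))
      i <- ij[1]; j <- ij[2]
      if (dist[i, j] > maxlim) break
      if (dist[i, j] > lim[j] || dmatched[i] || hits[j]) next
      dmatched[i] <- TRUE; hits[j] <- TRUE; massign[i] <- j
    }
  }
  list(counts = confusion_counts(tp = sum(hits), fp = sum(!dmatched),
                                 tn = 0L, fn = sum(!hits)),
       hits = hits, detection_matched = dmatched,
       matched_annotation = massign)
}

#' Non-maximum suppression of detections
#'
#' Candidates are per-slice components, so one nodule spanning several
#' slices produces a stack of near-duplicate detections. This merges them:
#' detections are visited in decreasing score order and each survivor
#' suppresses all others within `radius_mm` (3-D physical distance).
#'
#' @param detections data.frame with `slice`, `row`, `col`, `score`.
#' @param spacing voxel spacing `c(dz, dy, dx)` mm.
#' @param radius_mm suppression radius (default 10).
#' @return subset of `detections` (survivors, original order).
#' @export
merge_detections <- function(detections, spacing, radius_mm = 10) {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  pos <- cbind(detections$slice * spacing[1], detections$row * spacing[2],
               detections$col * spacing[3])
  keep <- rep(FALSE, n)
  alive <- rep(TRUE, n)
  ## ties broken by candidate order (slice, row, col ordering upstream)
  for (i in order(-detections$score, seq_len(n))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    d <- sqrt(rowSums((pos - matrix(pos[i, ], n, 3, byrow = TRUE))^2))
    alive[d <= radius_mm] <- FALSE
  }
  detections[keep, , drop = FALSE]
}

#' Threshold sweep
#'
#' One metrics row per threshold via [classify_at_threshold()] ->
#' [confusion_from_labels()] -> [compute_metrics()]. TPR is non-increasing
#' and specificity non-decreasing in the threshold.
#'
#' @param scores probabilities in `[0, 1]`.
#' @param truths logical truth labels, same length.
#' @param thresholds decision grid (default 0.1 to 0.9 by 0.1).
#' @return data.frame of metrics rows.
#' @export
threshold_sweep <- function(scores, truths,
                            thresholds = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(thresholds, function(th)
    compute_metrics(confusion_from_labels(classify_at_threshold(scores, th),
                                          truths),
                    threshold = th))
  do.call(rbind, rows)
}

#' Size-stratified sensitivity report
#'
#' Bins annotations by diameter into left-closed/right-open mm bins
#' (default `[3,5) [5,8) [8,10) [10,20) [20,Inf)`), tallies per-bin TP/FN
#' from the hit map and reports sensitivity as a percentage rounded half-up
#' to one decimal. Diameters below the lowest edge go to an explicit
#' `"<3 mm"` overflow bin, never silently dropped. A `Total` row closes the
#' table; bin tallies sum to it.
#'
#' @param hits logical hit map, one entry per annotation.
#' @param annotations annotation data.frame with `diameter_mm`.
#' @param bin_edges_mm increasing edges; last may be `Inf`.
#' @return data.frame with `bin`, `tp`, `fn`, `sensitivity_pct`.
#' @export
size_stratified_report <- function(hits, annotations,
                                   bin_edges_mm = c(3, 5, 8, 10, 20, Inf)) {
  stopifnot(length(hits) == nrow(annotations))
  dia <- annotations$diameter_mm
  if (any(is.na(dia))) stop("every annotation needs diameter_mm")
  labels <- c(sprintf("<%g mm", bin_edges_mm[1]),
              sprintf("%g-%g mm", head(bin_edges_mm, -1),
                      bin_edges_mm[-1]))
  labels[length(labels)] <-
    sprintf("> %g mm", bin_edges_mm[length(bin_edges_mm) - 1])
  idx <- findInterval(dia, bin_edges_mm) + 1L   # 1 = overflow below
  rows <- lapply(seq_along(labels), function(b) {
    sel <- idx == b
    tp <- sum(hits[sel]); fn <- sum(!hits[sel])
    data.frame(bin = labels[b], tp = tp, fn = fn,
               sensitivity_pct = if (tp + fn > 0)
                 round_half_up(100 * tp / (tp + fn), 1) else NA_real_)
  })
  out <- do.call(rbind, rows)
  ## drop the overflow bin when empty, keep the table at the printed layout
  if (out$tp[1] + out$fn[1] == 0) out <- out[-1, , drop = FALSE]
  total <- data.frame(bin = "Total", tp = sum(out$tp), fn = sum(out$fn),
                      sensitivity_pct = round_half_up(
                        100 * sum(out$tp) / max(1, sum(out$tp) + sum(out$fn)),
                        1))
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}

#' Format a metrics table as Markdown
#'
#' @param df data.frame (e.g. from [threshold_sweep()] or
#'   [size_stratified_report()]).
#' @param digits decimals for numeric columns (half-up).
#' @return character vector of Markdown lines.
#' @export
format_table_markdown <- function(df, digits = 5) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col) && !all(col == round(col), na.rm = TRUE))
      formatC(round_half_up(col, digits), format = "fg", digits = digits + 2)
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  fmt[is.na(df)] <- "NA"
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
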