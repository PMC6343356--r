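# Detection-evaluation calculus: the full metric set, matching, sweeps,
# size-stratified reports.

test_that("classification at a threshold is strictly greater-than", {
  expect_true(classify_at_threshold(0.6, 0.5))
  expect_false(classify_at_threshold(0.5, 0.5))   # equal -> normal tissue
  expect_false(classify_at_threshold(0.4, 0.5))
  expect_error(classify_at_threshold(1.2, 0.5), "0, 1")
  ## positives can only shrink as the threshold rises
  scores <- with_seed(31, runif(200))
  counts <- vapply(seq(0.1, 0.9, 0.1),
                   function(th) sum(classify_at_threshold(scores, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("confusion tallies match a loop oracle and conserve totals", {
  pred <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  cc <- confusion_from_labels(pred, truth)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(3, 2, 0, 0))
  for (seed in 1:4) {
    n <- 257
    pred <- with_seed(seed, runif(n) > 0.4)
    truth <- with_seed(seed + 100, runif(n) > 0.6)
    cc <- confusion_from_labels(pred, truth)
    ## independent element-by-element tally
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_len(n)) {
      if (pred[i] && truth[i]) tp <- tp + 1L
      else if (pred[i] && !truth[i]) fp <- fp + 1L
      else if (!pred[i] && !truth[i]) tn <- tn + 1L
      else fn <- fn + 1L
    }
    expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(tp, fp, tn, fn))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n)
  }
  expect_error(confusion_from_labels(c(TRUE), c(TRUE, FALSE)), "equal length")
})

test_that("the printed size-total sensitivity is reproduced: 305/321 -> 95.0", {
  m <- compute_metrics(confusion_counts(tp = 305, fp = 0, tn = 0, fn = 16))
  expect_equal(round_half_up(100 * m$sensitivity, 1), 95.0)
})

test_that("the printed best-threshold metric set is reproduced from its counts", {
  ## pre-trained model at threshold 0.6: (tp, fn, fp, tn) = (252, 41, 29, 271)
  m <- compute_metrics(confusion_counts(tp = 252, fp = 29, tn = 271, fn = 41))
  expect_printed(m$sensitivity, "0.86007")
  expect_printed(m$precision, "0.897")
  expect_printed(m$f_score, "0.87805")
  expect_printed(m$specificity, "0.903")
  expect_printed(m$false_positive_rate, "0.097")
  ## scratch model at threshold 0.5: (263, 30, 59, 241)
  m2 <- compute_metrics(confusion_counts(tp = 263, fp = 59, tn = 241, fn = 30))
  expect_printed(m2$f_score, "0.85528")
  expect_printed(m2$sensitivity, "0.89761")
  expect_printed(m2$precision, "0.817")
})

test_that("all 18 printed sweep rows reproduce to printed precision", {
  rows <- table2_rows()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    expect_equal(r$tp + r$fn, 293)   # 293 positives in the test set
    expect_equal(r$fp + r$tn, 300)   # 300 negatives
    m <- compute_metrics(confusion_counts(tp = r$tp, fp = r$fp, tn = r$tn,
                                          fn = r$fn))
    expect_printed(m$sensitivity, r$tpr)
    expect_printed(m$precision, r$precision)
    expect_printed(m$f_score, r$f)
  }
})

test_that("zero denominators yield NA metrics, never silent zeros", {
  m <- compute_metrics(confusion_counts(tp = 0, fp = 0, tn = 0, fn = 5))
  expect_equal(m$sensitivity, 0)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f_score))
  expect_true(is.na(m$specificity))
  m2 <- compute_metrics(confusion_counts(tp = 0, fp = 3, tn = 5, fn = 0))
  expect_true(is.na(m2$sensitivity))
  expect_equal(m2$precision, 0)
  expect_true(is.na(m2$f_score))
  ## both defined and zero -> F = 0
  m3 <- compute_metrics(confusion_counts(tp = 0, fp = 3, tn = 5, fn = 2))
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$precision, 0)
  expect_equal(m3$f_score, 0)
})

test_that("F is the harmonic mean, bounded by precision and TPR", {
  for (seed in 1:6) {
    v <- with_seed(seed, sample(0:120, 4))
    cc <- confusion_counts(tp = v[1] + 1, fp = v[2], tn = v[3], fn = v[4])
    m <- compute_metrics(cc)
    expect_equal(m$f_score,
                 2 / (1 / m$precision + 1 / m$sensitivity),
                 tolerance = 1e-12)
    expect_gte(m$f_score, min(m$precision, m$sensitivity) - 1e-12)
    expect_lte(m$f_score, max(m$precision, m$sensitivity) + 1e-12)
    if (!is.na(m$specificity))
      expect_equal(m$specificity + m$false_positive_rate, 1)
  }
})

test_that("average false positives per patient divide FP by patients", {
  expect_equal(average_false_positive(0, 10), 0)
  expect_equal(average_false_positive(10, 5), 2)
  expect_error(average_false_positive(3, 0), "n_patients")
  ## batch oracle over per-phantom counts
  fps <- c(2, 0, 5, 1, 3, 4)
  expect_equal(average_false_positive(sum(fps), length(fps)), mean(fps))
})

test_that("detection matching follows the greedy nearest-first contract", {
  sp <- c(2.5, 0.7, 0.7)
  ann <- data.frame(slice = c(10, 20), row = c(50, 80), col = c(50, 80),
                    diameter_mm = c(8, 6))
  ## exact hit
  m <- match_detections(data.frame(slice = 10, row = 50, col = 50), ann[1, ],
                        spacing = sp)
  expect_equal(c(m$counts$tp, m$counts$fp, m$counts$fn), c(1, 0, 0))
  ## no detections: all annotations are misses
  m2 <- match_detections(data.frame(slice = integer(0), row = integer(0),
                                    col = integer(0)),
                         rbind(ann, ann), spacing = sp)
  expect_equal(m2$counts$fn, 4)
  ## two detections inside one nodule: one TP, one FP
  two <- data.frame(slice = c(10, 10), row = c(50, 52), col = c(50, 50))
  m3 <- match_detections(two, ann[1, ], spacing = sp)
  expect_equal(c(m3$counts$tp, m3$counts$fp), c(1, 1))
  ## nearest detection takes the annotation
  expect_true(m3$detection_matched[1])
  expect_false(m3$detection_matched[2])
  ## beyond max(radius, 1.5 mm): a miss plus a false positive
  far <- data.frame(slice = 10, row = 50 + 10, col = 50)  # 7 mm > 4 mm radius
  m4 <- match_detections(far, ann[1, ], spacing = sp)
  expect_equal(c(m4$counts$tp, m4$counts$fp, m4$counts$fn), c(0, 1, 1))
  ## the 1.5 mm floor applies to tiny nodules
  tiny <- data.frame(slice = 10, row = 50, col = 50, diameter_mm = 1)
  near <- data.frame(slice = 10, row = 51, col = 50)      # 0.7 mm away
  expect_equal(match_detections(near, tiny, spacing = sp)$counts$tp, 1)
  expect_error(match_detections(two, ann), "spacing")
})

test_that("non-maximum suppression keeps the best of each cluster", {
  sp <- c(2.5, 0.7, 0.7)
  det <- data.frame(slice = c(10, 11, 12, 30), row = c(50, 50, 51, 50),
                    col = c(50, 50, 50, 50),
                    score = c(0.4, 0.9, 0.5, 0.3))
  out <- merge_detections(det, sp, radius_mm = 10)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$score, c(0.9, 0.3))
  expect_identical(merge_detections(det[0, ], sp), det[0, ])
})

test_that("threshold sweeps are monotone and reproduce a constructed row", {
  ## one positive scoring 0.9, one negative scoring 0.1
  sw <- threshold_sweep(c(0.9, 0.1), c(TRUE, FALSE))
  expect_equal(sw$sensitivity[sw$threshold < 0.9], rep(1, 8))
  expect_equal(sw$sensitivity[sw$threshold == 0.9], 0)
  ## seeded random scores: TPR non-increasing, specificity non-decreasing
  for (seed in 1:3) {
    scores <- with_seed(seed, runif(300))
    truth <- with_seed(seed + 50, runif(300) > 0.5)
    sw <- threshold_sweep(scores, truth)
    expect_true(all(diff(sw$sensitivity) <= 1e-12))
    expect_true(all(diff(sw$specificity) >= -1e-12))
  }
  ## scores constructed to hit the printed (252, 41, 29, 271) row at 0.6
  scores <- c(rep(0.65, 252), rep(0.55, 41), rep(0.65, 29), rep(0.55, 271))
  truth <- c(rep(TRUE, 252 + 41), rep(FALSE, 29 + 271))
  row <- threshold_sweep(scores, truth, thresholds = 0.6)
  expect_equal(c(row$tp, row$fn, row$fp, row$tn), c(252, 41, 29, 271))
  expect_printed(row$f_score, "0.87805")
})

test_that("size-stratified report reproduces the printed per-bin table", {
  t1 <- table1_rows()
  diameters <- c(4, 6.5, 9, 15, 25)      # one per bin
  ann <- do.call(rbind, lapply(seq_len(5), function(b)
    data.frame(diameter_mm = rep(diameters[b], t1$tp[b] + t1$fn[b]))))
  hits <- unlist(lapply(seq_len(5), function(b)
    rep(c(TRUE, FALSE), c(t1$tp[b], t1$fn[b]))))
  rep <- size_stratified_report(hits, ann)
  expect_equal(rep$tp[1:5], t1$tp)
  expect_equal(rep$fn[1:5], t1$fn)
  expect_equal(rep$sensitivity_pct[1:5], t1$sensitivity_pct)
  total <- rep[rep$bin == "Total", ]
  expect_equal(c(total$tp, total$fn), c(305, 16))
  expect_equal(total$sensitivity_pct, 95.0)
})

test_that("binning is left-closed, overflow-binned, and conserves totals", {
  ann <- data.frame(diameter_mm = c(2, 3, 4.999, 5, 8, 10, 20, 40))
  hits <- c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  rep <- size_stratified_report(hits, ann)
  expect_equal(rep$bin[1], "<3 mm")            # never silently dropped
  expect_equal(rep$tp[rep$bin == "3-5 mm"], 2) # 3 and 4.999 both in [3,5)
  expect_equal(rep$tp[rep$bin == "5-8 mm"], 1) # 5 is left-closed
  total <- rep[rep$bin == "Total", ]
  expect_equal(total$tp + total$fn, nrow(ann))
  expect_equal(sum(rep$tp[rep$bin != "Total"]), total$tp)
  ## seeded random hit maps match a brute-force binning oracle
  edges <- c(3, 5, 8, 10, 20, Inf)
  for (seed in 1:3) {
    ann <- with_seed(seed, data.frame(diameter_mm = runif(80, 1, 30)))
    hits <- with_seed(seed + 9, runif(80) > 0.3)
    rep <- size_stratified_report(hits, ann)
    for (b in seq_len(5)) {
      sel <- ann$diameter_mm >= edges[b] &
        ann$diameter_mm < edges[b + 1]
      lab <- rep$bin[b + as.integer(any(ann$diameter_mm < 3))]
      expect_equal(rep$tp[rep$bin == lab], sum(hits[sel]))
      expect_equal(rep$fn[rep$bin == lab], sum(!hits[sel]))
    }
  }
})

test_that("metric tables render as Markdown", {
  sw <- threshold_sweep(c(0.9, 0.2, 0.7), c(TRUE, FALSE, TRUE),
                        thresholds = c(0.5))
  md <- format_table_markdown(sw)
  expect_match(md[1], "^\\| threshold")
  expect_match(md[2], "^\\|---")
  expect_length(md, 3)
})

test_that("confusion counts reject negatives and non-integers", {
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
  expect_error(confusion_counts(1.5, 0, 0, 0), "non-negative")
})
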