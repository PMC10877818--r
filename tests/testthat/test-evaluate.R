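test_that("concordance table buckets offsets at -5..0 plus others", {
  ct <- concordance_from_offsets(c(0L))
  expect_equal(attr(ct, "within_window_percent"), 100)
  expect_equal(ct$count[ct$timing == "0"], 1)

  ct2 <- concordance_from_offsets(c(-6L, -5L, 0L, 1L))
  expect_equal(ct2$count[ct2$timing == "others"], 2)
  expect_equal(attr(ct2, "within_window_count"), 2)

  expect_error(concordance_from_offsets(integer(0)),
               class = "lhsurge_empty_table")
  # raw counts always sum to the total; rounded percentages to 100 +/- rows
  set.seed(3)
  for (i in 1:20) {
    off <- sample(-8:3, sample(3:40, 1), replace = TRUE)
    ct <- concordance_from_offsets(off)
    expect_equal(sum(ct$count), length(off))
    expect_lte(abs(sum(ct$percent) - 100), nrow(ct))
  }
})

test_that("compute_offsets pairs channels and logs exclusions by reason", {
  calls <- make_paired_calls(c(-5, -2, 0, 1))
  # knock out one cycle per exclusion path
  calls$ovulation_day[calls$channel == "urine" &
                        calls$cycle_id == "C001"] <- NA_integer_
  calls$pattern[calls$channel == "urine" & calls$cycle_id == "C001"] <- "none"
  calls$n_observed[calls$channel == "vaginal_discharge" &
                     calls$cycle_id == "C002"] <- 0L
  calls$first_surge_day[calls$channel == "vaginal_discharge" &
                          calls$cycle_id == "C003"] <- NA_integer_
  ct <- compute_offsets(calls)
  expect_equal(attr(ct, "total"), 1)
  excl <- attr(ct, "exclusions")
  expect_setequal(excl$reason, c("no_ulh_surge", "no_vd_data", "no_vlh_surge"))
  expect_error(compute_offsets(make_paired_calls(numeric(0))),
               class = "lhsurge_empty_table")
})

test_that("pooled-variance t-test matches the closed form and handles degeneracy", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- students_t_test(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(t_hand, 4), tolerance = 1e-9)

  same <- students_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(inf <- students_t_test(c(1, 1), c(2, 2)))
  expect_equal(inf$p_value, 0)
  expect_error(students_t_test(1, c(1, 2)),
               class = "lhsurge_insufficient_data")

  welch <- students_t_test(c(1, 2, 3, 9), c(4, 5, 6), var_equal = FALSE)
  ref <- stats::t.test(c(1, 2, 3, 9), c(4, 5, 6))
  expect_equal(welch$statistic, unname(ref$statistic))
})

test_that("ROC sweep reproduces the worked examples", {
  expect_equal(roc_analysis(c(0.9, 0.8), c(0.1, 0.2))$auc, 1)
  expect_equal(roc_analysis(c(0.6, 0.4), c(0.5, 0.3))$auc, 0.75)
  expect_equal(roc_analysis(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  pts <- roc_analysis(c(0.6, 0.4), c(0.5, 0.3))$points
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(pts$fpr[nrow(pts)], 1)
})

test_that("trapezoid AUC equals the Mann-Whitney exceedance probability", {
  set.seed(17)
  for (i in 1:200) {
    pos <- sample(seq(0, 1, by = 0.25), sample(1:8, 1), replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.25), sample(1:8, 1), replace = TRUE)
    auc <- roc_analysis(pos, neg)$auc
    cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:25) {
    pos <- runif(sample(3:10, 1))
    neg <- runif(sample(3:10, 1))
    ref <- suppressMessages(pROC::auc(
      response = c(rep("neg", length(neg)), rep("pos", length(pos))),
      predictor = c(neg, pos), levels = c("neg", "pos"), direction = "<"))
    expect_equal(roc_analysis(pos, neg)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("Youden cutoff maximizes J over an exhaustive scan, ties to the lower cutoff", {
  y <- youden_cutoff(c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(y$cutoff, 0.8)
  expect_equal(y$j, 1)

  set.seed(29)
  for (i in 1:200) {
    pos <- sample(seq(0, 1, by = 0.1), sample(2:8, 1), replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), sample(2:8, 1), replace = TRUE)
    y <- suppressWarnings(youden_cutoff(pos, neg))
    # independent exhaustive scan
    cand <- sort(unique(c(pos, neg)))
    j_scan <- vapply(cand, function(cut) {
      mean(pos >= cut) + mean(neg < cut) - 1
    }, numeric(1))
    expect_equal(y$j, max(j_scan), tolerance = 1e-12)
    expect_equal(y$cutoff, min(cand[j_scan >= max(j_scan) - 1e-12]))
    # metric single-source-of-truth: accuracy recomputed from the same matrix
    m <- y$metrics
    expect_equal(m$proportion[m$metric == "accuracy"],
                 (y$tp + y$tn) / (y$tp + y$tn + y$fp + y$fn))
  }

  expect_warning(youden_cutoff(c(1, 1), c(1, 1)), "Youden")
})

test_that("confusion metrics use round-half-up integer percentages", {
  m <- confusion_metrics(tp = 25, fn = 4, tn = 24, fp = 5)
  expect_equal(m$percent[m$metric == "sensitivity"], 86)  # 25/29
  expect_equal(m$percent[m$metric == "specificity"], 83)  # 24/29
  expect_equal(m$percent[m$metric == "ppv"], 83)          # 25/30
  expect_equal(m$percent[m$metric == "npv"], 86)          # 24/28
  expect_equal(round_half_up(24.5), 25)  # not banker's rounding
  expect_error(confusion_metrics(-1, 0, 0, 0),
               class = "lhsurge_validation_error")
})

test_that("evaluate_cohort assembles per-cycle groups and the funnel", {
  # well-separated zero-noise cohort, vaginal lag 0 -> offset -1 everywhere
  cfg <- noise_free_config()
  cfg$n_participants <- 12
  cfg$baseline_cv <- 0.2   # vary per-cycle levels so the groups are non-degenerate
  cfg$amplitude_cv <- 0.2
  cfg$seed <- 61
  cohort <- generate_cohort(cfg)
  series <- preprocess_cohort(cohort$samples, lods = zero_lods)
  calls <- call_cohort(series)
  ev <- evaluate_cohort(calls, series)
  expect_equal(ev$funnel$n, c(12, 12, 12, 12))
  expect_equal(attr(ev$concordance, "within_window_percent"), 100)
  expect_true(all(ev$groups$offset == -1))
  expect_equal(ev$auc, 1)
  expect_equal(nrow(ev$groups), 12)
  expect_lt(ev$t_test$p_value, 0.01)
  expect_lt(ev$t_test$statistic, 0)  # baseline group below surge group

  # every offset outside the window -> 0% within
  calls_out <- make_paired_calls(rep(-6, 5))
  ct <- compute_offsets(calls_out)
  expect_equal(attr(ct, "within_window_percent"), 0)
  expect_equal(ct$count[ct$timing == "others"], 5)

  # fewer than 2 cycles with both channels callable -> hard error
  calls_bad <- make_paired_calls(c(-1, -2, -3))
  calls_bad$first_surge_day[calls_bad$channel == "vaginal_discharge"] <- NA_integer_
  calls_bad$pattern[calls_bad$channel == "vaginal_discharge"] <- "none"
  expect_error(evaluate_cohort(calls_bad, series),
               class = "lhsurge_insufficient_cohort")
})
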