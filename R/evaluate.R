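#' Concordance table of first-surge offsets
#'
#' Tabulates per-cycle offsets of the vaginal-discharge first surge day
#' relative to the urine-derived ovulation day into the fertile-window
#' buckets -5, -4, ..., -1, 0 (0 = ovulation day) plus an `others` bucket
#' for any offset outside that range, with percentages rounded half-up to
#' integers. An offset within -5..0 means the first vaginal surge fell
#' inside the six-day fertile window.
#'
#' @param offsets Integer vector, one signed offset per cycle
#'   (`first_surge_day - ovulation_day`; negative = before ovulation).
#' @return A `concordance_table` tibble with columns `timing`, `count`,
#'   `percent`, and attributes `total`, `within_window_count`,
#'   `within_window_percent`.
#' @examples
#' concordance_from_offsets(rep(c(-5, -2, 0, 1), c(3, 4, 2, 1)))
#' @export
concordance_from_offsets <- function(offsets) {
  if (length(offsets) == 0 || any(is.na(offsets))) {
    abort("`offsets` must be a nonempty vector without NA",
          class = "lhsurge_empty_table")
  }
  levels <- c(as.character(-5:0), "others")
  lab <- ifelse(offsets >= -5 & offsets <= 0, as.character(offsets), "others")
  counts <- table(factor(lab, levels = levels))
  total <- length(offsets)
  out <- tibble::tibble(
    timing = levels,
    count = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / total)
  )
  within <- sum(out$count[out$timing != "others"])
  structure(out,
            total = total,
            within_window_count = within,
            within_window_percent = round_half_up(100 * within / total),
            class = c("concordance_table", class(out)))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Timing of first vaginal-discharge LH surge relative to ovulation day\n")
  NextMethod()
  cat(sprintf("within fertile window: %d/%d cycles (%d%%)\n",
              attr(x, "within_window_count"), attr(x, "total"),
              attr(x, "within_window_percent")))
  invisible(x)
}

#' Offsets of the vaginal first surge relative to ovulation
#'
#' Pairs each cycle's urine call with its vaginal-discharge call, computes
#' the signed offset `first_surge_day - ovulation_day`, and tabulates it
#' with [concordance_from_offsets()]. Cycles lacking a urinary ovulation day
#' or a vaginal first surge day are excluded and recorded (with a reason) in
#' the `exclusions` attribute; per-cycle offsets are kept in the `cycles`
#' attribute.
#'
#' @param calls Per-cycle call tibble from [call_cohort()] covering both
#'   channels.
#' @return A `concordance_table` (see [concordance_from_offsets()]).
#' @export
compute_offsets <- function(calls) {
  u <- calls |>
    dplyr::filter(.data$channel == "urine") |>
    dplyr::select("participant_id", "cycle_id",
                  u_pattern = "pattern", "ovulation_day")
  v <- calls |>
    dplyr::filter(.data$channel == "vaginal_discharge") |>
    dplyr::select("participant_id", "cycle_id", v_pattern = "pattern",
                  "first_surge_day", v_n_observed = "n_observed")
  j <- dplyr::inner_join(u, v, by = c("participant_id", "cycle_id"))
  j$reason <- dplyr::case_when(
    is.na(j$ovulation_day) ~ "no_ulh_surge",
    j$v_n_observed == 0 ~ "no_vd_data",
    is.na(j$first_surge_day) ~ "no_vlh_surge",
    TRUE ~ NA_character_
  )
  eligible <- j[is.na(j$reason), ]
  if (nrow(eligible) == 0) {
    abort("no cycles with both a urinary ovulation day and a vaginal first surge day",
          class = "lhsurge_empty_table")
  }
  eligible$offset <- as.integer(eligible$first_surge_day - eligible$ovulation_day)
  ct <- concordance_from_offsets(eligible$offset)
  attr(ct, "cycles") <- eligible[, c("participant_id", "cycle_id", "offset")]
  attr(ct, "exclusions") <- j[!is.na(j$reason),
                              c("participant_id", "cycle_id", "reason")]
  ct
}

#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sample t-test (two-sided), with Welch's
#' unequal-variance form available by flag. Degenerate inputs are handled
#' explicitly: two constant groups with equal means give `t = 0, p = 1`;
#' constant groups with unequal means give an infinite statistic and
#' `p = 0` with a warning.
#'
#' @param group_a,group_b Numeric vectors, each with at least two
#'   non-missing values.
#' @param var_equal Use the pooled-variance (classical Student) form
#'   (default `TRUE`); `FALSE` gives Welch.
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `method`.
#' @examples
#' students_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
students_t_test <- function(group_a, group_b, var_equal = TRUE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 non-missing values",
          class = "lhsurge_insufficient_data")
  }
  method <- if (var_equal) "Student (pooled variance)" else "Welch"
  df <- length(a) + length(b) - 2
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = df, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b), method = method))
    }
    warn("both groups are constant with unequal means; t is infinite")
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, df = df,
                p_value = 0, mean_a = mean(a), mean_b = mean(b),
                method = method))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       method = method)
}

#' ROC analysis of a diagnostic marker
#'
#' Sweeps the decision threshold over every observed value; a case is
#' test-positive when its value is greater than or equal to the threshold.
#' Returns the ROC points anchored at (0,0) and (1,1) and the area under
#' the curve by the trapezoid rule, which equals the Mann-Whitney
#' exceedance probability P(positive > negative) + 0.5 P(tie).
#'
#' @param positives Marker values of the positive class (surge days).
#' @param negatives Marker values of the negative class (baselines).
#' @return List with `points` (tibble `threshold`, `sensitivity`,
#'   `specificity`, `tpr`, `fpr`, ordered by descending threshold) and
#'   `auc`.
#' @examples
#' roc_analysis(c(0.6, 0.4), c(0.5, 0.3))$auc
#' @export
roc_analysis <- function(positives, negatives) {
  pos <- positives[!is.na(positives)]
  neg <- negatives[!is.na(negatives)]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both groups must be nonempty", class = "lhsurge_insufficient_data")
  }
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  points <- tibble::tibble(
    threshold = thr, sensitivity = tpr, specificity = 1 - fpr,
    tpr = tpr, fpr = fpr
  )
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Youden-optimal cutoff and diagnostic metrics
#'
#' Picks the threshold maximizing the Youden index
#' J = sensitivity + specificity - 1 over the observed values; ties break
#' toward the lower cutoff (higher sensitivity). Reports the confusion
#' matrix and metrics at that cutoff; a test-positive is a value greater
#' than or equal to the cutoff.
#'
#' @inheritParams roc_analysis
#' @return List with `cutoff`, `j`, the confusion counts `tp`, `fn`, `tn`,
#'   `fp`, and `metrics`, a tibble from [confusion_metrics()].
#' @export
youden_cutoff <- function(positives, negatives) {
  pos <- positives[!is.na(positives)]
  neg <- negatives[!is.na(negatives)]
  roc <- roc_analysis(pos, neg)
  pts <- roc$points[is.finite(roc$points$threshold), ]
  j <- pts$sensitivity + pts$specificity - 1
  jmax <- max(j)
  if (jmax <= 0) {
    warn("Youden index is 0 at every cutoff; the marker does not separate the groups")
  }
  cutoff <- min(pts$threshold[j >= jmax - 1e-12])
  tp <- sum(pos >= cutoff)
  fn <- sum(pos < cutoff)
  tn <- sum(neg < cutoff)
  fp <- sum(neg >= cutoff)
  list(cutoff = cutoff, j = jmax, tp = tp, fn = fn, tn = tn, fp = fp,
       metrics = confusion_metrics(tp, fn, tn, fp))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy, each as the exact proportion and as an integer percentage
#' (round half-up). All five derive from the same four counts, so they are
#' mutually consistent by construction.
#'
#' @param tp,fn,tn,fp Nonnegative integer counts.
#' @return Tibble with columns `metric`, `numerator`, `denominator`,
#'   `proportion`, `percent`.
#' @examples
#' confusion_metrics(tp = 25, fn = 4, tn = 24, fp = 5)
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    abort("confusion counts must be nonnegative integers",
          class = "lhsurge_validation_error")
  }
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn,
           accuracy = tp + tn)
  den <- c(sensitivity = tp + fn, specificity = tn + fp, ppv = tp + fp,
           npv = tn + fn, accuracy = tp + fn + tn + fp)
  prop <- ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    metric = names(num),
    numerator = unname(num),
    denominator = unname(den),
    proportion = unname(prop),
    percent = round_half_up(100 * unname(prop))
  )
}

#' Evaluate vaginal-discharge LH against urinary ovulation timing
#'
#' Cohort-level evaluation mirroring the full analysis: the exclusion
#' funnel (all cycles, cycles with a urinary surge, of those the cycles
#' with vaginal-discharge data, of those the cycles with a vaginal surge),
#' the fertile-window concordance table, and the diagnostic comparison of
#' per-cycle vaginal baseline values against per-cycle first-surge values
#' (Student's t-test, ROC/AUC, Youden cutoff with confusion metrics). One
#' baseline value and one surge value enter per eligible cycle.
#'
#' @param calls Per-cycle calls from [call_cohort()], both channels.
#' @param series Normalized series from [preprocess_cohort()] (used to look
#'   up the vaginal value on each first surge day).
#' @param var_equal Passed to [students_t_test()].
#' @return Object of class `lh_evaluation`: list with `funnel`,
#'   `concordance`, `groups`, `t_test`, `roc`, `auc`, `youden`,
#'   `exclusions`.
#' @export
evaluate_cohort <- function(calls, series, var_equal = TRUE) {
  u <- calls |>
    dplyr::filter(.data$channel == "urine") |>
    dplyr::select("participant_id", "cycle_id", u_pattern = "pattern",
                  "ovulation_day")
  v <- calls |>
    dplyr::filter(.data$channel == "vaginal_discharge") |>
    dplyr::select("participant_id", "cycle_id", v_pattern = "pattern",
                  v_baseline = "baseline", "first_surge_day",
                  v_n_observed = "n_observed")
  j <- dplyr::inner_join(u, v, by = c("participant_id", "cycle_id"))

  has_usurge <- !is.na(j$ovulation_day)
  has_vd <- has_usurge & j$v_n_observed > 0
  has_vsurge <- has_vd & !is.na(j$first_surge_day)
  funnel <- tibble::tibble(
    stage = c("cycles_total", "ulh_surge_detected", "vd_data_available",
              "vlh_surge_detected"),
    n = c(nrow(j), sum(has_usurge), sum(has_vd), sum(has_vsurge))
  )
  eligible <- j[has_vsurge, ]
  if (nrow(eligible) < 2) {
    abort("insufficient cohort: fewer than 2 cycles with both channels callable",
          class = "lhsurge_insufficient_cohort")
  }

  vd <- series[series$channel == "vaginal_discharge", ]
  surge_value <- mapply(function(pid, cid, day) {
    val <- vd$value[vd$participant_id == pid & vd$cycle_id == cid &
                      vd$day == day]
    if (length(val) == 1) val else NA_real_
  }, eligible$participant_id, eligible$cycle_id, eligible$first_surge_day)

  groups <- tibble::tibble(
    participant_id = eligible$participant_id,
    cycle_id = eligible$cycle_id,
    offset = as.integer(eligible$first_surge_day - eligible$ovulation_day),
    baseline = eligible$v_baseline,
    surge = unname(surge_value)
  )
  concordance <- compute_offsets(calls)
  t_test <- students_t_test(groups$baseline, groups$surge,
                            var_equal = var_equal)
  roc <- roc_analysis(positives = groups$surge, negatives = groups$baseline)
  youden <- youden_cutoff(positives = groups$surge,
                          negatives = groups$baseline)
  structure(
    list(funnel = funnel, concordance = concordance, groups = groups,
         t_test = t_test, roc = roc, auc = roc$auc, youden = youden,
         exclusions = attr(concordance, "exclusions")),
    class = "lh_evaluation"
  )
}

#' @export
print.lh_evaluation <- function(x, ...) {
  cat("<lh_evaluation>\n")
  cat("Exclusion funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-22s %d\n", x$funnel$stage[i], x$funnel$n[i]))
  }
  cat(sprintf("Within fertile window: %d%%\n",
              attr(x$concordance, "within_window_percent")))
  cat(sprintf("AUC %.3f; Youden cutoff %.3g mIU/mg; t = %.2f (df %s, p = %.3g)\n",
              x$auc, x$youden$cutoff, x$t_test$statistic,
              format(x$t_test$df), x$t_test$p_value))
  m <- x$youden$metrics
  cat(sprintf("sens %d%% spec %d%% ppv %d%% npv %d%% acc %d%%\n",
              m$percent[1], m$percent[2], m$percent[3], m$percent[4],
              m$percent[5]))
  invisible(x)
}
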