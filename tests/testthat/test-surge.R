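test_that("peak maximum takes the earliest day on ties", {
  expect_equal(find_peak_maximum(make_series(c(1, 1, 1, 1, 10, 1, 1, 1, 1, 1))), 14)
  expect_equal(find_peak_maximum(make_series(rep(5, 10))), 10)
  expect_equal(find_peak_maximum(make_series(c(1, 2, 10, 3, 10, 1, 1, 1, 1, 1))), 12)
  expect_error(find_peak_maximum(make_series(rep(NA_real_, 10))),
               class = "lhsurge_empty_series")
})

test_that("baseline is the mean of the observed flank days, peak excluded", {
  s <- make_series(c(1, 1, 1, 1, 10, 1, 1, 1, 1, 1))
  expect_equal(estimate_baseline(s, 14), list(baseline = 1, n_days = 4L))
  s2 <- make_series(c(2, 2, 2, 4, 20, 6, 2, 2, 2, 2))
  expect_equal(estimate_baseline(s2, 14)$baseline, (2 + 4 + 6 + 2) / 4)
  # peak at the window edge: only the two right-hand flanks exist
  s3 <- make_series(c(9, 2, 4, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(estimate_baseline(s3, 10), list(baseline = 3, n_days = 2L))
  # no flank observed -> undetermined
  s4 <- make_series(c(9, NA, NA, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(estimate_baseline(s4, 10)$n_days, 0L)
})

test_that("elevated days require both threshold conditions, strictly", {
  s <- make_series(c(1, 1, 1, 1, 10, 1, 1, 1, 1, 1))
  expect_equal(detect_elevated_days(s, baseline = 1, peak_day = 14), 14L)
  s2 <- make_series(c(1, 1, 4, 5, 4, 1, 1, 1, 1, 1))
  expect_equal(detect_elevated_days(s2, baseline = 1, peak_day = 13),
               c(12L, 13L, 14L))
  flat <- make_series(rep(3, 10))
  expect_equal(detect_elevated_days(flat, baseline = 3, peak_day = 10),
               integer(0))
  # condition 2 alone is not enough: high baseline blocks a shallow peak
  s3 <- make_series(c(5, 5, 5, 5, 9, 5, 5, 5, 5, 5))
  expect_equal(detect_elevated_days(s3, baseline = 5, peak_day = 14),
               integer(0))
})

test_that("raw amplitude convention anchors condition 1 to the raw maximum", {
  s <- make_series(c(1, 1, 1, 4, 10, 1, 1, 1, 1, 1))
  # excess: day 13 excess 3 > 0.3*9 = 2.7 -> elevated
  expect_equal(detect_elevated_days(s, 1, 14, "excess"), c(13L, 14L))
  # raw: day 13 value 4 > 0.3*10 = 3 and > 2 -> also elevated; but a value
  # of 2.8 passes excess arithmetic differently from raw
  s2 <- make_series(c(1, 1, 1, 2.8, 10, 1, 1, 1, 1, 1))
  expect_equal(detect_elevated_days(s2, 1, 14, "excess"), 14L)   # 1.8 < 2.7
  expect_equal(detect_elevated_days(s2, 1, 14, "raw"), 14L)      # 2.8 < 3
  s3 <- make_series(c(1, 1, 1, 3.5, 10, 1, 1, 1, 1, 1))
  expect_equal(detect_elevated_days(s3, 1, 14, "excess"), 14L)   # 2.5 < 2.7
  expect_equal(detect_elevated_days(s3, 1, 14, "raw"), c(13L, 14L))
})

test_that("pattern classification separates sharp, broad, multiple, none", {
  obs <- 10:19
  expect_equal(classify_pattern(14L, obs), "sharp_single")
  expect_equal(classify_pattern(c(12L, 13L, 14L), obs), "broad_single")
  expect_equal(classify_pattern(c(11L, 15L, 16L), obs), "multiple")
  expect_equal(classify_pattern(integer(0), obs), "none")
  # an unobserved gap cannot split a run
  expect_equal(classify_pattern(c(12L, 14L), setdiff(obs, 13L)),
               "broad_single")
  expect_equal(classify_pattern(c(12L, 14L), obs), "multiple")
})

test_that("ovulation day is the day after the final elevated day", {
  expect_equal(determine_ovulation_day(14L), 15L)
  expect_equal(determine_ovulation_day(c(12L, 13L, 14L)), 15L)
  expect_equal(determine_ovulation_day(c(11L, 15L, 16L)), 17L)
  expect_true(is.na(determine_ovulation_day(integer(0))))
})

test_that("the fertile window is the 5 days before ovulation plus ovulation day", {
  expect_equal(fertile_window(15), 10:15)
  expect_equal(fertile_window(16), 11:16)
  expect_length(fertile_window(13), 6)
})

test_that("call_cycle composes the rules and degrades without aborting", {
  s <- make_series(c(1, 1, 1, 1, 10, 1, 1, 1, 1, 1))
  call <- call_cycle(s, "urine")
  expect_equal(call$pattern, "sharp_single")
  expect_equal(call$elevated_days[[1]], 14L)
  expect_equal(call$ovulation_day, 15L)
  expect_equal(c(call$fw_start, call$fw_end), c(10L, 15L))
  expect_false(call$ovulation_past_window)

  # all censored/unobserved -> none, with a reason, no error
  empty <- call_cycle(make_series(rep(NA_real_, 10)), "urine")
  expect_equal(empty$pattern, "none")
  expect_equal(empty$exclusion_reason, "no_observed_days")

  # isolated peak with no observed flank -> baseline undetermined
  iso <- make_series(c(9, NA, NA, 1, 1, 1, 1, 1, 1, 1))
  iso_call <- call_cycle(iso, "urine")
  expect_equal(iso_call$pattern, "none")
  expect_equal(iso_call$exclusion_reason, "baseline_undetermined")

  # vaginal channel reports first surge day, not ovulation
  v <- call_cycle(make_series(c(1, 1, 5, 6, 1, 1, 1, 1, 1, 1)),
                  "vaginal_discharge")
  expect_equal(v$first_surge_day, 12L)
  expect_true(is.na(v$ovulation_day))

  # elevated last window day pushes ovulation one day past the window
  late <- call_cycle(make_series(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 10)), "urine")
  expect_equal(late$ovulation_day, 20L)
  expect_true(late$ovulation_past_window)
})

test_that("elevated-day calls equal the brute-force oracle on random series", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(4:10, 1)
    values <- runif(n, 0.1, 10)
    observed <- runif(n) > 0.15
    if (!any(observed)) observed[1] <- TRUE
    s <- make_series(values, days = seq(10, length.out = n),
                     observed = observed)
    baseline <- runif(1, 0.05, max(values[observed]))
    conv <- sample(c("excess", "raw"), 1)
    peak <- find_peak_maximum(s)
    expect_identical(
      detect_elevated_days(s, baseline, peak, conv),
      oracle_elevated(s$day, s$value, s$observed, baseline, conv))
  }
})

test_that("surge calls are invariant to a positive rescaling of the series", {
  set.seed(7)
  for (i in 1:50) {
    values <- runif(10, 0.2, 1) + c(rep(0, 4), runif(1, 2, 8), rep(0, 5))
    s <- make_series(values)
    scale <- runif(1, 0.01, 100)
    a <- call_cycle(s, "urine")
    b <- call_cycle(make_series(values * scale), "urine")
    expect_identical(a$elevated_days, b$elevated_days)
    expect_identical(a$pattern, b$pattern)
    expect_identical(a$ovulation_day, b$ovulation_day)
  }
})

test_that("every called cycle carries exactly one of the four pattern classes", {
  cohort <- generate_cohort(generator_config(n_participants = 20,
                                             cycles_per_participant = 2,
                                             p_missing_day = 0.15,
                                             noise_cv = 0.4, seed = 55))
  calls <- call_cohort(preprocess_cohort(cohort$samples))
  expect_true(all(calls$pattern %in%
                    c("sharp_single", "broad_single", "multiple", "none")))
  expect_equal(calls$pattern == "none", calls$n_elevated == 0)
  expect_equal(is.na(calls$first_surge_day), calls$pattern == "none")
})
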