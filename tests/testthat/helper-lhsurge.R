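# Shared fixtures, all built in code.

# A one-cycle/one-channel normalized series tibble.
make_series <- function(values, days = seq(10L, length.out = length(values)),
                        observed = !is.na(values)) {
  tibble::tibble(day = as.integer(days), value = values,
                 observed = observed & !is.na(values))
}

# LODs that disable censoring entirely (the "no censoring" condition of the
# closure property).
zero_lods <- list(ulh = 0, creatinine = 0, vlh = 0, total_protein = 0)

# Generator config with every stochastic nuisance switched off: one pattern,
# fixed cycle length, unit creatinine, zero noise. Produces exactly
# reproducible normalized values (ratio 1 baseline, 10 at a sharp peak on
# day 14 when cycle_length = 29).
noise_free_config <- function(pattern = "sharp_single", ...) {
  probs <- c(sharp_single = 0, broad_single = 0, multiple = 0)
  probs[pattern] <- 1
  generator_config(
    n_participants = 1, cycles_per_participant = 1,
    cycle_length_mean = 29, cycle_length_sd = 0,
    baseline_mean = 1, baseline_cv = 0,
    amplitude_mean = 9, amplitude_cv = 0,
    pattern_probs = probs,
    vlh_lag_probs = stats::setNames(c(0, 0, 0, 0, 1, 0, 0, 0, 0),
                                    as.character(-4:4)),
    noise_cv = 0, creatinine_cv = 0, protein_cv = 0,
    p_missing_day = 0, p_collection_fail = 0,
    ...
  )
}

# Per-cycle call rows for both channels with the given first-surge offsets
# relative to a urinary ovulation day of 16; enough structure for
# compute_offsets()/evaluate_cohort() input contracts.
make_paired_calls <- function(offsets) {
  n <- length(offsets)
  ids <- sprintf("C%03d", seq_len(n))
  base <- tibble::tibble(
    participant_id = ids, cycle_id = ids, n_observed = 10L,
    peak_day = 14L, baseline = 1, n_baseline_days = 4L,
    elevated_days = replicate(n, 14L, simplify = FALSE), n_elevated = 1L,
    pattern = "sharp_single", first_surge_day = NA_integer_,
    ovulation_day = NA_integer_, fw_start = NA_integer_,
    fw_end = NA_integer_, ovulation_past_window = FALSE,
    exclusion_reason = NA_character_
  )
  u <- dplyr::mutate(base, channel = "urine", ovulation_day = 16L,
                     fw_start = 11L, fw_end = 16L)
  v <- dplyr::mutate(base, channel = "vaginal_discharge",
                     first_surge_day = 16L + as.integer(offsets))
  dplyr::bind_rows(u, v)
}

# Independent brute-force oracle for the two surge conditions, evaluated
# day by day, straight from their definition.
oracle_elevated <- function(days, values, observed, baseline,
                            convention = "excess") {
  obs_days <- days[observed]
  obs_vals <- values[observed]
  peak <- obs_days[which(obs_vals == max(obs_vals))[1]]
  vmax <- obs_vals[obs_days == peak]
  out <- integer()
  for (i in seq_along(obs_days)) {
    v <- obs_vals[i]
    c1 <- if (convention == "excess") {
      (v - baseline) > 0.3 * (vmax - baseline)
    } else {
      v > 0.3 * vmax
    }
    if (c1 && v > 2 * baseline) out <- c(out, obs_days[i])
  }
  sort(out)
}
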