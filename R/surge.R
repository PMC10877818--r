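#' Day of the peak maximum
#'
#' Returns the observed day carrying the maximum normalized LH value; ties
#' break to the earliest day so calls are deterministic.
#'
#' @param series Tibble for one cycle/channel with columns `day`, `value`,
#'   `observed`.
#' @return A single day index.
#' @export
find_peak_maximum <- function(series) {
  obs <- series[series$observed & !is.na(series$value), ]
  if (nrow(obs) == 0) {
    abort("series has no observed days", class = "lhsurge_empty_series")
  }
  obs <- obs[order(obs$day), ]
  obs$day[which.max(obs$value)]
}

#' Baseline LH level around the peak
#'
#' The baseline is the mean normalized LH over the two days before and two
#' days after the peak maximum (`peak_day + c(-2, -1, 1, 2)`), the peak day
#' itself excluded. At the edge of the collection window, or when some flank
#' days are unobserved, the mean is taken over whichever of the four days are
#' observed; if none is, the baseline is undetermined and the cycle cannot be
#' called.
#'
#' @inheritParams find_peak_maximum
#' @param peak_day Day index from [find_peak_maximum()].
#' @return A list with `baseline` (`NA` if undetermined) and `n_days`, the
#'   number of flank days the mean used (0--4).
#' @export
estimate_baseline <- function(series, peak_day) {
  flank <- peak_day + c(-2L, -1L, 1L, 2L)
  obs <- series[series$observed & !is.na(series$value) &
                  series$day %in% flank, ]
  if (nrow(obs) == 0) {
    return(list(baseline = NA_real_, n_days = 0L))
  }
  list(baseline = mean(obs$value), n_days = nrow(obs))
}

#' Elevated (surge) days of a cycle
#'
#' A day is part of the LH surge when both conditions hold, with strict
#' inequalities: (1) its rise above baseline exceeds 30% of the maximum peak
#' amplitude, and (2) its value exceeds twice the baseline. Under the default
#' `"excess"` convention the peak amplitude is the peak value minus the
#' baseline and condition (1) compares each day's excess over baseline
#' against 30% of it; under `"raw"` condition (1) compares the day's value
#' against 30% of the raw peak value.
#'
#' @inheritParams estimate_baseline
#' @param baseline Baseline level from [estimate_baseline()]; must be > 0.
#' @param amplitude_convention `"excess"` (default) or `"raw"`; see Details.
#' @return Sorted integer vector of elevated day indices (possibly empty).
#' @export
detect_elevated_days <- function(series, baseline, peak_day,
                                 amplitude_convention = c("excess", "raw")) {
  amplitude_convention <- match.arg(amplitude_convention)
  if (!is.finite(baseline) || baseline <= 0) {
    abort("`baseline` must be a positive number",
          class = "lhsurge_validation_error")
  }
  obs <- series[series$observed & !is.na(series$value), ]
  vmax <- obs$value[obs$day == peak_day]
  if (length(vmax) != 1) {
    abort("`peak_day` is not an observed day of the series",
          class = "lhsurge_validation_error")
  }
  cond1 <- if (amplitude_convention == "excess") {
    (obs$value - baseline) > 0.3 * (vmax - baseline)
  } else {
    obs$value > 0.3 * vmax
  }
  cond2 <- obs$value > 2 * baseline
  sort(as.integer(obs$day[cond1 & cond2]))
}

#' Classify the peak morphology of a cycle
#'
#' Elevated days are grouped into runs; two elevated days belong to
#' different runs only when at least one observed, non-elevated day lies
#' strictly between them (a gap made of unobserved days does not split a
#' run, since separation cannot be confirmed there). One run of a single day
#' is a sharp single peak; one run of two or more days is a broad single
#' peak; two or more runs are multiple peaks; no elevated days means no
#' discernible peak.
#'
#' @param elevated_days Sorted integer vector from [detect_elevated_days()].
#' @param observed_days Integer vector of all observed day indices.
#' @return One of `"sharp_single"`, `"broad_single"`, `"multiple"`, `"none"`.
#' @export
classify_pattern <- function(elevated_days, observed_days) {
  k <- length(elevated_days)
  if (k == 0) return("none")
  e <- sort(elevated_days)
  splits <- vapply(seq_len(max(k - 1, 0)), function(i) {
    between <- observed_days[observed_days > e[i] & observed_days < e[i + 1]]
    any(!(between %in% e)) && length(between) > 0
  }, logical(1))
  n_runs <- 1L + sum(splits)
  if (n_runs >= 2) "multiple" else if (k >= 2) "broad_single" else "sharp_single"
}

#' Ovulation day from the urinary surge
#'
#' The ovulation day is the day after the last elevated urinary LH day,
#' whatever the peak morphology; absent when the cycle shows no surge.
#'
#' @inheritParams classify_pattern
#' @return Day index, or `NA` when `elevated_days` is empty.
#' @export
determine_ovulation_day <- function(elevated_days) {
  if (length(elevated_days) == 0) return(NA_integer_)
  as.integer(max(elevated_days) + 1L)
}

#' The six-day fertile window
#'
#' The fertile window comprises the five days before ovulation plus the day
#' of ovulation.
#'
#' @param ovulation_day Day index of ovulation.
#' @return Integer vector of the six window days, ending on `ovulation_day`.
#' @examples
#' fertile_window(15)
#' @export
fertile_window <- function(ovulation_day) {
  if (is.na(ovulation_day)) return(NA_integer_)
  seq(as.integer(ovulation_day) - 5L, as.integer(ovulation_day))
}

#' Call the surge, pattern and ovulation day for one cycle
#'
#' Composes the full per-cycle algorithm: peak maximum, baseline from the
#' flanking days, elevated-day detection under the two threshold conditions,
#' morphology classification, and — for the urine channel — the ovulation
#' day (last elevated day + 1) and fertile window. For the
#' vaginal-discharge channel the first surge day (earliest elevated day, the
#' proxy for the first positive home test) is reported instead of an
#' ovulation day. Cycles whose baseline cannot be determined, or that show
#' no elevated day, are returned with `pattern = "none"` and an exclusion
#' reason rather than an error, so cohort-level processing never aborts.
#'
#' @inheritParams find_peak_maximum
#' @param channel `"urine"` or `"vaginal_discharge"`.
#' @inheritParams detect_elevated_days
#' @return One-row tibble: `channel`, `n_observed`, `peak_day`, `baseline`,
#'   `n_baseline_days`, `elevated_days` (list column), `n_elevated`,
#'   `pattern`, `first_surge_day`, `ovulation_day` (urine only), `fw_start`,
#'   `fw_end`, `ovulation_past_window`, `exclusion_reason`.
#' @export
call_cycle <- function(series, channel = c("urine", "vaginal_discharge"),
                       amplitude_convention = c("excess", "raw")) {
  channel <- match.arg(channel)
  amplitude_convention <- match.arg(amplitude_convention)
  res <- tibble::tibble(
    channel = channel, n_observed = 0L, peak_day = NA_integer_,
    baseline = NA_real_, n_baseline_days = 0L,
    elevated_days = list(integer()), n_elevated = 0L, pattern = "none",
    first_surge_day = NA_integer_, ovulation_day = NA_integer_,
    fw_start = NA_integer_, fw_end = NA_integer_,
    ovulation_past_window = FALSE, exclusion_reason = NA_character_
  )
  obs <- series$observed & !is.na(series$value)
  res$n_observed <- sum(obs)
  if (res$n_observed == 0) {
    res$exclusion_reason <- "no_observed_days"
    return(res)
  }
  res$peak_day <- find_peak_maximum(series)
  bl <- estimate_baseline(series, res$peak_day)
  res$n_baseline_days <- bl$n_days
  if (bl$n_days == 0 || !is.finite(bl$baseline) || bl$baseline <= 0) {
    res$exclusion_reason <- "baseline_undetermined"
    return(res)
  }
  res$baseline <- bl$baseline
  elev <- detect_elevated_days(series, bl$baseline, res$peak_day,
                               amplitude_convention)
  if (length(elev) == 0) {
    res$exclusion_reason <- "no_surge"
    return(res)
  }
  res$elevated_days <- list(elev)
  res$n_elevated <- length(elev)
  res$pattern <- classify_pattern(elev, series$day[obs])
  res$first_surge_day <- as.integer(min(elev))
  if (channel == "urine") {
    ov <- determine_ovulation_day(elev)
    res$ovulation_day <- ov
    fw <- fertile_window(ov)
    res$fw_start <- fw[1]
    res$fw_end <- fw[length(fw)]
    res$ovulation_past_window <- ov > max(series$day)
  }
  res
}

#' Call every cycle of a cohort on both channels
#'
#' @param series Long tibble from [preprocess_cohort()] (columns
#'   `participant_id`, `cycle_id`, `channel`, `day`, `value`, `observed`).
#' @inheritParams detect_elevated_days
#' @return Tibble of one [call_cycle()] row per cycle and channel.
#' @export
call_cohort <- function(series, amplitude_convention = c("excess", "raw")) {
  amplitude_convention <- match.arg(amplitude_convention)
  stopifnot(all(c("participant_id", "cycle_id", "channel", "day", "value",
                  "observed") %in% names(series)))
  series |>
    dplyr::group_by(.data$participant_id, .data$cycle_id, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      out <- call_cycle(df, channel = key$channel,
                        amplitude_convention = amplitude_convention)
      out$channel <- NULL
      out
    }) |>
    dplyr::ungroup()
}
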