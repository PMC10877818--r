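#' Limit of detection by the 3-sigma rule
#'
#' Computes the assay limit of detection (LOD) from blank measurements as
#' `mean(blanks) + 3 * sd(blanks)`, with the sample standard deviation
#' (n - 1 denominator).
#'
#' @param blanks Numeric vector of at least two nonnegative blank
#'   measurements.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return The LOD, a single nonnegative number.
#' @examples
#' compute_lod(c(0.008, 0.010, 0.012))
#' @export
compute_lod <- function(blanks, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.numeric(blanks) || any(!is.finite(blanks)) || any(blanks < 0)) {
    abort("`blanks` must be finite nonnegative measurements",
          class = "lhsurge_validation_error")
  }
  n <- length(blanks)
  if (n < 2) {
    abort("at least 2 blank measurements are required to compute an LOD",
          class = "lhsurge_insufficient_data")
  }
  s <- sd(blanks)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  mean(blanks) + 3 * s
}

#' Substitute values below the limit of detection
#'
#' Values strictly below `lod` are replaced by `lod` and flagged; values
#' equal to or above it pass through unchanged ("lower than" is strict).
#' `NA` values stay `NA` and are never flagged. The operation is idempotent.
#'
#' @param values Nonnegative numeric vector of measured concentrations.
#' @param lod Nonnegative limit of detection, same units as `values`.
#' @return A list with `value` (substituted vector) and `censored`
#'   (logical flags, `TRUE` where substitution happened).
#' @examples
#' censor_below_lod(c(0.005, 0.5, 0.016), lod = 0.016)
#' @export
censor_below_lod <- function(values, lod) {
  if (length(lod) != 1 || !is.finite(lod) || lod < 0) {
    abort("`lod` must be a single nonnegative number",
          class = "lhsurge_validation_error")
  }
  if (!is.numeric(values) || any(values < 0, na.rm = TRUE)) {
    abort("`values` must be nonnegative", class = "lhsurge_validation_error")
  }
  censored <- !is.na(values) & values < lod
  out <- values
  out[censored] <- lod
  list(value = out, censored = censored)
}

#' Flag below-LOD values and failed collections in daily samples
#'
#' Applies the per-assay LODs to a tibble of daily records and sets the QC
#' status: a day is `collection_failed` when both the analyte and its
#' normalizer fall below their LODs, `missing` when either value is absent,
#' and `ok` otherwise. Only `ok` days carry usable measurements downstream;
#' on those days a single below-LOD value is substituted by the LOD rather
#' than dropped.
#'
#' @param samples Tibble with numeric columns `analyte` and `normalizer`.
#' @param lod_analyte,lod_normalizer Limits of detection for the two assays.
#' @return `samples` with added columns `analyte_below_lod`,
#'   `normalizer_below_lod` and `qc_status`.
#' @export
qc_daily_samples <- function(samples, lod_analyte, lod_normalizer) {
  stopifnot(all(c("analyte", "normalizer") %in% names(samples)))
  a <- censor_below_lod(samples$analyte, lod_analyte)
  n <- censor_below_lod(samples$normalizer, lod_normalizer)
  samples$analyte_below_lod <- a$censored
  samples$normalizer_below_lod <- n$censored
  samples$qc_status <- dplyr::case_when(
    is.na(samples$analyte) | is.na(samples$normalizer) ~ "missing",
    a$censored & n$censored ~ "collection_failed",
    TRUE ~ "ok"
  )
  samples
}

#' Normalize one cycle's analyte series by its concentration normalizer
#'
#' Produces the normalized LH-ratio trajectory for a single cycle and
#' channel: per observed day, the LOD-substituted analyte divided by the
#' LOD-substituted normalizer (uLH/Cr for urine, vLH/Pro for vaginal
#' discharge, in mIU per mg). Days that are absent, missing, or failed
#' collections appear in the output with `observed = FALSE`; nothing is ever
#' imputed.
#'
#' @param samples Tibble for one cycle with columns `day`, `analyte`,
#'   `normalizer` (raw concentrations; `NA` = missing).
#' @param lod_analyte,lod_normalizer Limits of detection.
#' @param window Inclusive day range `c(first, last)` the series should span;
#'   defaults to the range of `samples$day`.
#' @return Tibble with one row per window day: `day`, `value` (normalized
#'   ratio, `NA` when unobserved), `observed`, `qc_status`.
#' @examples
#' normalize_cycle(tibble::tibble(day = 10:12, analyte = c(2, 0.06, 1),
#'                                normalizer = c(1, 0.5, 2)),
#'                 lod_analyte = 0.04, lod_normalizer = 0.01)
#' @export
normalize_cycle <- function(samples, lod_analyte, lod_normalizer,
                            window = NULL) {
  stopifnot(all(c("day", "analyte", "normalizer") %in% names(samples)))
  window <- window %||% range(samples$day)
  qc <- qc_daily_samples(samples, lod_analyte, lod_normalizer)
  a <- censor_below_lod(qc$analyte, lod_analyte)$value
  n <- censor_below_lod(qc$normalizer, lod_normalizer)$value
  ok <- qc$qc_status == "ok"
  if (any(ok & !is.na(n) & n == 0)) {
    d <- qc$day[ok & !is.na(n) & n == 0][1]
    abort(sprintf("zero normalizer after LOD substitution on day %d; cannot normalize", d),
          class = "lhsurge_division_error")
  }
  value <- ifelse(ok, a / n, NA_real_)
  out <- tibble::tibble(day = as.integer(seq(window[1], window[2])))
  idx <- match(out$day, qc$day)
  out$value <- value[idx]
  out$qc_status <- ifelse(is.na(idx), "missing", qc$qc_status[idx])
  out$observed <- !is.na(out$value)
  out[, c("day", "value", "observed", "qc_status")]
}

#' Normalize a whole cohort on both channels
#'
#' Runs [normalize_cycle()] per cycle for the urine channel (uLH over
#' creatinine) and the vaginal-discharge channel (vLH over total protein),
#' returning a tidy long table of normalized series.
#'
#' @param raw Per-day raw samples tibble as produced by [generate_cohort()]
#'   or [read_cohort_samples()].
#' @param lods Named list of LODs: `ulh`, `creatinine`, `vlh`,
#'   `total_protein` (raw concentration units).
#' @param window Inclusive day range; defaults to the range observed in `raw`.
#' @return Tibble with columns `participant_id`, `cycle_id`, `channel`
#'   (`"urine"` or `"vaginal_discharge"`), `day`, `value`, `observed`,
#'   `qc_status`.
#' @export
preprocess_cohort <- function(raw,
                              lods = list(ulh = 0.04, creatinine = 0.01,
                                          vlh = 0.04, total_protein = 0.01),
                              window = NULL) {
  need <- c("participant_id", "cycle_id", "day", "ulh", "creatinine",
            "vlh", "total_protein")
  stopifnot(all(need %in% names(raw)))
  window <- window %||% range(raw$day)
  one_channel <- function(analyte_col, norm_col, lod_a, lod_n, channel) {
    raw |>
      dplyr::select(dplyr::all_of(c("participant_id", "cycle_id", "day",
                                    analyte = analyte_col,
                                    normalizer = norm_col))) |>
      dplyr::group_by(.data$participant_id, .data$cycle_id) |>
      dplyr::group_modify(function(df, key) {
        normalize_cycle(df, lod_a, lod_n, window = window)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(channel = channel, .after = "cycle_id")
  }
  dplyr::bind_rows(
    one_channel("ulh", "creatinine", lods$ulh, lods$creatinine, "urine"),
    one_channel("vlh", "total_protein", lods$vlh, lods$total_protein,
                "vaginal_discharge")
  )
}
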