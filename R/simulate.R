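#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set controlling
#' [generate_cohort()]. The defaults emulate the cohort the pipeline was
#' designed for: 35 participants contributing 55 cycles (20 with two cycles,
#' 15 with one), cycle length 30 +/- 2.4 days bounded to the normal 25--38 day
#' range, and daily collection on cycle days 10 through 19. Hormone-level
#' parameters (baseline, amplitude, noise, lag distribution) are illustrative
#' defaults, not estimates from any study: the generator exists to exercise
#' the pipeline against known ground truth, not to model endocrine physiology.
#'
#' @param n_participants Number of participants.
#' @param cycles_per_participant Integer scalar or vector (recycled to
#'   `n_participants`) giving how many cycles each participant contributes.
#' @param cycle_length_mean,cycle_length_sd Mean and SD of cycle length in
#'   days; draws are rounded and rejected outside
#'   `[cycle_length_min, cycle_length_max]`.
#' @param cycle_length_min,cycle_length_max Bounds on cycle length (days).
#' @param collection_window Inclusive 1-based day range of daily sampling,
#'   as `c(first, last)`; days are counted from the first day of menstruation.
#' @param baseline_mean,baseline_cv Mean and coefficient of variation of the
#'   per-cycle baseline normalized LH ratio (mIU per mg normalizer), drawn
#'   lognormally.
#' @param amplitude_mean,amplitude_cv Mean/CV of the per-cycle surge amplitude
#'   (excess over baseline, same units). Draws are floored at
#'   `min_amplitude_ratio` times the cycle's baseline so every generated surge
#'   is detectable by the threshold rules in the absence of noise.
#' @param min_amplitude_ratio Lower bound on amplitude/baseline (default 3).
#' @param pattern_probs Named probabilities over the three peak morphologies
#'   `sharp_single`, `broad_single`, `multiple`; must sum to 1.
#' @param broad_width_days Width (consecutive elevated days) of a broad
#'   single peak; integer >= 2. Widths above 2 inflate the baseline estimate
#'   so that the literal detection rule can no longer recover the full run
#'   (see the methods vignette); the default 2 preserves the closure property.
#' @param n_extra_peaks Number of secondary peaks in a `multiple` pattern
#'   (integer >= 1), placed before the primary peak at 40--80% amplitude with
#'   at least two non-elevated days of separation.
#' @param vlh_lag_probs Named probabilities for the vaginal-discharge channel
#'   lag in days relative to the urinary template, over the integers -4..+4
#'   (negative = vLH earlier). The whole template is shifted, not reshaped.
#' @param vlh_scale Multiplicative scale mapping the urinary normalized-ratio
#'   scale onto the vaginal-discharge one (vLH/Pro values are roughly an
#'   order of magnitude smaller than uLH/Cr).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   assay noise applied independently per day and channel.
#' @param creatinine_mean,creatinine_cv Daily urinary creatinine (mg/mL).
#' @param protein_mean,protein_cv Daily total protein of the discharge
#'   extract (mg/mL).
#' @param lod_analyte,lod_normalizer Limits of detection used by the
#'   generator when emulating failed collections (raw concentration units).
#' @param p_missing_day Probability a day's record is entirely missing.
#' @param p_collection_fail Probability (per day, per channel) that a
#'   collection fails, i.e. both analyte and normalizer fall below their LODs.
#' @param p_no_vd Probability a whole cycle lacks vaginal-discharge samples.
#' @param seed Optional integer seed; when set, [generate_cohort()] is fully
#'   reproducible.
#'
#' @return A validated list of class `generator_config`.
#' @seealso [generate_cohort()], [generate_cycle()]
#' @export
generator_config <- function(n_participants = 35,
                             cycles_per_participant = c(rep(2L, 20), rep(1L, 15)),
                             cycle_length_mean = 30,
                             cycle_length_sd = 2.4,
                             cycle_length_min = 25,
                             cycle_length_max = 38,
                             collection_window = c(10L, 19L),
                             baseline_mean = 1,
                             baseline_cv = 0.25,
                             amplitude_mean = 9,
                             amplitude_cv = 0.3,
                             min_amplitude_ratio = 3,
                             pattern_probs = c(sharp_single = 0.5,
                                               broad_single = 0.25,
                                               multiple = 0.25),
                             broad_width_days = 2L,
                             n_extra_peaks = 1L,
                             vlh_lag_probs = c(`-4` = 0.08, `-3` = 0.10,
                                               `-2` = 0.14, `-1` = 0.30,
                                               `0` = 0.14, `1` = 0.10,
                                               `2` = 0.06, `3` = 0.04,
                                               `4` = 0.04),
                             vlh_scale = 0.06,
                             noise_cv = 0.2,
                             creatinine_mean = 1,
                             creatinine_cv = 0.3,
                             protein_mean = 0.5,
                             protein_cv = 0.3,
                             lod_analyte = 0.04,
                             lod_normalizer = 0.01,
                             p_missing_day = 0.05,
                             p_collection_fail = 0.02,
                             p_no_vd = 0,
                             seed = NULL) {
  cfg <- list(
    n_participants = n_participants,
    cycles_per_participant = cycles_per_participant,
    cycle_length_mean = cycle_length_mean,
    cycle_length_sd = cycle_length_sd,
    cycle_length_min = cycle_length_min,
    cycle_length_max = cycle_length_max,
    collection_window = as.integer(collection_window),
    baseline_mean = baseline_mean,
    baseline_cv = baseline_cv,
    amplitude_mean = amplitude_mean,
    amplitude_cv = amplitude_cv,
    min_amplitude_ratio = min_amplitude_ratio,
    pattern_probs = pattern_probs,
    broad_width_days = as.integer(broad_width_days),
    n_extra_peaks = as.integer(n_extra_peaks),
    vlh_lag_probs = vlh_lag_probs,
    vlh_scale = vlh_scale,
    noise_cv = noise_cv,
    creatinine_mean = creatinine_mean,
    creatinine_cv = creatinine_cv,
    protein_mean = protein_mean,
    protein_cv = protein_cv,
    lod_analyte = lod_analyte,
    lod_normalizer = lod_normalizer,
    p_missing_day = p_missing_day,
    p_collection_fail = p_collection_fail,
    p_no_vd = p_no_vd,
    seed = seed
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("invalid generator config: `%s` %s", field, msg),
          class = "lhsurge_config_error")
  }
  if (length(cfg$n_participants) != 1 || is.na(cfg$n_participants) ||
      cfg$n_participants < 0 || cfg$n_participants %% 1 != 0) {
    bad("n_participants", "must be a single nonnegative integer")
  }
  if (any(is.na(cfg$cycles_per_participant)) ||
      any(cfg$cycles_per_participant < 0) ||
      any(cfg$cycles_per_participant %% 1 != 0)) {
    bad("cycles_per_participant", "must be nonnegative integers")
  }
  w <- cfg$collection_window
  if (length(w) != 2 || any(is.na(w)) || w[1] > w[2] || w[1] < 1) {
    bad("collection_window", "must be a nonempty 1-based day range c(first, last)")
  }
  if (abs(sum(cfg$pattern_probs) - 1) > 1e-9) {
    bad("pattern_probs", "must sum to 1")
  }
  if (!setequal(names(cfg$pattern_probs),
                c("sharp_single", "broad_single", "multiple"))) {
    bad("pattern_probs", "must be named sharp_single/broad_single/multiple")
  }
  if (abs(sum(cfg$vlh_lag_probs) - 1) > 1e-9) {
    bad("vlh_lag_probs", "must sum to 1")
  }
  if (!identical(names(cfg$vlh_lag_probs), as.character(-4:4))) {
    bad("vlh_lag_probs", "must be named over the integers -4..4")
  }
  for (p in c("pattern_probs", "vlh_lag_probs", "p_missing_day",
              "p_collection_fail", "p_no_vd")) {
    v <- cfg[[p]]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      bad(p, "must lie in [0, 1]")
    }
  }
  for (p in c("cycle_length_mean", "baseline_mean", "amplitude_mean",
              "min_amplitude_ratio", "vlh_scale", "creatinine_mean",
              "protein_mean")) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0) bad(p, "must be > 0")
  }
  for (p in c("cycle_length_sd", "baseline_cv", "amplitude_cv", "noise_cv",
              "creatinine_cv", "protein_cv", "lod_analyte", "lod_normalizer")) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 0) bad(p, "must be >= 0")
  }
  if (cfg$cycle_length_min > cfg$cycle_length_max) {
    bad("cycle_length_min", "must not exceed cycle_length_max")
  }
  if (cfg$broad_width_days < 2) bad("broad_width_days", "must be >= 2")
  if (cfg$n_extra_peaks < 1) bad("n_extra_peaks", "must be >= 1")
  invisible(cfg)
}

draw_cycle_length <- function(cfg) {
  if (cfg$cycle_length_sd == 0) {
    return(as.integer(min(max(round(cfg$cycle_length_mean),
                              cfg$cycle_length_min), cfg$cycle_length_max)))
  }
  for (i in seq_len(1000)) {
    l <- round(rnorm(1, cfg$cycle_length_mean, cfg$cycle_length_sd))
    if (l >= cfg$cycle_length_min && l <= cfg$cycle_length_max) {
      return(as.integer(l))
    }
  }
  as.integer(round(cfg$cycle_length_mean))
}

# Peak template: integer days paired with relative excess (fraction of the
# cycle amplitude). The primary peak sits near cycle_length - 15 so that the
# implied ovulation day tracks the usual 14-day luteal phase; it is clamped
# two days into the window so the baseline flanks exist.
draw_template <- function(cfg, pattern, cycle_length) {
  ws <- cfg$collection_window[1]
  we <- cfg$collection_window[2]
  p <- min(max(cycle_length - 15L, ws + 2L), we - 1L)
  if (pattern == "sharp_single") {
    days <- p
    rel <- 1
  } else if (pattern == "broad_single") {
    # slight downward taper keeps the peak-maximum day unambiguous, and the
    # clamp keeps every run day's baseline flanks inside the window, so the
    # detection rules recover the run exactly at zero noise
    p <- min(p, we - cfg$broad_width_days)
    days <- p:(p + cfg$broad_width_days - 1L)
    rel <- seq(1, 0.94, length.out = length(days))
  } else {
    sec <- p - 3L - 2L * (seq_len(cfg$n_extra_peaks) - 1L)
    days <- c(sec, p)
    rel <- c(runif(cfg$n_extra_peaks, 0.4, 0.8), 1)
  }
  list(days = as.integer(days), rel = rel, peak_day = p)
}

#' Generate one synthetic cycle with its ground truth
#'
#' Draws a single menstrual cycle under `config`: a peak morphology
#' (sharp/broad/multiple), per-cycle baseline and amplitude, a
#' vaginal-discharge lag, then daily raw assay values (analyte x normalizer)
#' with multiplicative lognormal noise, missing days and failed collections.
#' Uses the current R random number generator state; seed via `set.seed()`
#' or let [generate_cohort()] manage the seed.
#'
#' @param config A [generator_config()].
#' @param participant_id,cycle_id Identifiers stamped on the output rows.
#' @return A list with `samples`, a tibble of one row per collection-window
#'   day (columns `participant_id`, `cycle_id`, `day`, `ulh`, `creatinine`,
#'   `vlh`, `total_protein`; `NA` for missing days), and `truth`, a one-row
#'   tibble with the drawn pattern, elevated-day sets (list columns), the
#'   true ovulation day (last elevated urinary day + 1) and the true first
#'   vaginal surge day, plus truncation flags for template days that fell
#'   outside the collection window.
#' @export
generate_cycle <- function(config, participant_id = "P01",
                           cycle_id = "P01_C1") {
  validate_generator_config(config)
  cfg <- config
  window <- seq(cfg$collection_window[1], cfg$collection_window[2])
  n <- length(window)

  cycle_length <- draw_cycle_length(cfg)
  pattern <- sample(names(cfg$pattern_probs), 1, prob = cfg$pattern_probs)
  tmpl <- draw_template(cfg, pattern, cycle_length)

  b_u <- rlnorm_mean_cv(1, cfg$baseline_mean, cfg$baseline_cv)
  a_u <- max(rlnorm_mean_cv(1, cfg$amplitude_mean, cfg$amplitude_cv),
             cfg$min_amplitude_ratio * b_u)
  b_v <- rlnorm_mean_cv(1, cfg$baseline_mean, cfg$baseline_cv)
  a_v <- max(rlnorm_mean_cv(1, cfg$amplitude_mean, cfg$amplitude_cv),
             cfg$min_amplitude_ratio * b_v)
  lag <- sample(-4:4, 1, prob = cfg$vlh_lag_probs)

  days_v <- tmpl$days + lag
  elev_u <- sort(intersect(tmpl$days, window))
  elev_v <- sort(intersect(days_v, window))
  truncated_u <- !all(tmpl$days %in% window)
  truncated_v <- !all(days_v %in% window)

  rel_at <- function(days_tmpl, query) {
    r <- numeric(length(query))
    m <- match(query, days_tmpl)
    r[!is.na(m)] <- tmpl$rel[m[!is.na(m)]]
    r
  }
  u_norm <- (b_u + a_u * rel_at(tmpl$days, window)) *
    rlnorm_mean_cv(n, 1, cfg$noise_cv)
  v_norm <- cfg$vlh_scale * (b_v + a_v * rel_at(tmpl$days, window - lag)) *
    rlnorm_mean_cv(n, 1, cfg$noise_cv)

  creatinine <- rlnorm_mean_cv(n, cfg$creatinine_mean, cfg$creatinine_cv)
  protein <- rlnorm_mean_cv(n, cfg$protein_mean, cfg$protein_cv)
  ulh <- u_norm * creatinine
  vlh <- v_norm * protein

  # failed collections: both analyte and normalizer pushed below their LODs
  fail_u <- runif(n) < cfg$p_collection_fail
  fail_v <- runif(n) < cfg$p_collection_fail
  sub_lod <- function(k, lod) runif(k, 0, max(lod, .Machine$double.eps)) * 0.9
  ulh[fail_u] <- sub_lod(sum(fail_u), cfg$lod_analyte)
  creatinine[fail_u] <- sub_lod(sum(fail_u), cfg$lod_normalizer)
  vlh[fail_v] <- sub_lod(sum(fail_v), cfg$lod_analyte)
  protein[fail_v] <- sub_lod(sum(fail_v), cfg$lod_normalizer)

  miss <- runif(n) < cfg$p_missing_day
  ulh[miss] <- NA_real_
  creatinine[miss] <- NA_real_
  vlh[miss] <- NA_real_
  protein[miss] <- NA_real_

  has_vd <- runif(1) >= cfg$p_no_vd
  if (!has_vd) {
    vlh[] <- NA_real_
    protein[] <- NA_real_
  }

  samples <- tibble::tibble(
    participant_id = participant_id,
    cycle_id = cycle_id,
    day = as.integer(window),
    ulh = ulh,
    creatinine = creatinine,
    vlh = vlh,
    total_protein = protein
  )
  truth <- tibble::tibble(
    participant_id = participant_id,
    cycle_id = cycle_id,
    cycle_length = cycle_length,
    true_pattern = pattern,
    baseline_u = b_u,
    amplitude_u = a_u,
    baseline_v = cfg$vlh_scale * b_v,
    amplitude_v = cfg$vlh_scale * a_v,
    vlh_lag = as.integer(lag),
    true_elevated_days_u = list(as.integer(elev_u)),
    true_ovulation_day = as.integer(max(elev_u) + 1L),
    true_elevated_days_v = list(as.integer(elev_v)),
    true_first_surge_day_v = if (length(elev_v)) as.integer(min(elev_v)) else NA_integer_,
    truncated_u = truncated_u,
    truncated_v = truncated_v,
    has_vd = has_vd
  )
  list(samples = samples, truth = truth)
}

#' Generate a synthetic cohort of paired uLH/vLH daily series
#'
#' Draws `n_participants` participants, each contributing the configured
#' number of cycles, and returns the raw daily samples alongside a
#' ground-truth manifest with one row per cycle. Fully reproducible when
#' `config$seed` is set.
#'
#' @param config A [generator_config()].
#' @return An object of class `lh_cohort`: a list with `samples` (per-day raw
#'   assay tibble), `truth` (per-cycle ground-truth manifest) and `config`.
#' @examples
#' cohort <- generate_cohort(generator_config(
#'   n_participants = 3, cycles_per_participant = 1, seed = 1))
#' cohort$truth[, c("cycle_id", "true_pattern", "true_ovulation_day")]
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  per <- rep_len(config$cycles_per_participant, max(n, 1L))
  samples <- list()
  truth <- list()
  k <- 0
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    for (j in seq_len(per[i])) {
      k <- k + 1
      cyc <- generate_cycle(config, pid, sprintf("%s_C%d", pid, j))
      samples[[k]] <- cyc$samples
      truth[[k]] <- cyc$truth
    }
  }
  if (k == 0) {
    empty <- generate_cycle_schema()
    samples <- empty$samples
    truth <- empty$truth
  } else {
    samples <- dplyr::bind_rows(samples)
    truth <- dplyr::bind_rows(truth)
  }
  structure(list(samples = samples, truth = truth, config = config),
            class = "lh_cohort")
}

generate_cycle_schema <- function() {
  list(
    samples = tibble::tibble(
      participant_id = character(), cycle_id = character(), day = integer(),
      ulh = double(), creatinine = double(), vlh = double(),
      total_protein = double()
    ),
    truth = tibble::tibble(
      participant_id = character(), cycle_id = character(),
      cycle_length = integer(), true_pattern = character(),
      baseline_u = double(), amplitude_u = double(),
      baseline_v = double(), amplitude_v = double(), vlh_lag = integer(),
      true_elevated_days_u = list(), true_ovulation_day = integer(),
      true_elevated_days_v = list(), true_first_surge_day_v = integer(),
      truncated_u = logical(), truncated_v = logical(), has_vd = logical()
    )
  )
}

#' @export
print.lh_cohort <- function(x, ...) {
  cat(sprintf("<lh_cohort> %d cycles from %d participants, days %d-%d\n",
              nrow(x$truth), length(unique(x$truth$participant_id)),
              x$config$collection_window[1], x$config$collection_window[2]))
  if (nrow(x$truth)) {
    print(table(pattern = x$truth$true_pattern))
  }
  invisible(x)
}

#' Write / read a synthetic cohort as plain CSV + YAML
#'
#' `write_cohort()` writes `samples.csv` (per-day raw records, empty cells
#' for missing days), `truth.csv` (per-cycle ground truth, day sets joined
#' with `;`) and `config.yaml` into `dir`. `read_cohort_samples()` reads a
#' per-day samples CSV of the same schema (user data or generated), failing
#' with a named file/line on malformed rows.
#'
#' @param cohort An `lh_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the paths invisibly;
#'   `read_cohort_samples()` returns the samples tibble.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lh_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  readr::write_csv(cohort$samples, paths[["samples"]], na = "")
  truth_flat <- cohort$truth
  for (col in c("true_elevated_days_u", "true_elevated_days_v")) {
    truth_flat[[col]] <- vapply(truth_flat[[col]], paste, "", collapse = ";")
  }
  readr::write_csv(truth_flat, paths[["truth"]], na = "")
  cfg <- unclass(cohort$config)
  cfg$pattern_probs <- as.list(cfg$pattern_probs)
  cfg$vlh_lag_probs <- as.list(cfg$vlh_lag_probs)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' @rdname write_cohort
#' @param path Path to a per-day samples CSV with columns `participant_id`,
#'   `cycle_id`, `day`, `ulh`, `creatinine`, `vlh`, `total_protein`.
#' @export
read_cohort_samples <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    cycle_id = readr::col_character(),
    day = readr::col_integer(),
    ulh = readr::col_double(),
    creatinine = readr::col_double(),
    vlh = readr::col_double(),
    total_protein = readr::col_double()
  ), na = c("", "NA"))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in %s at line %d: %s", path,
                  probs$row[1], probs$expected[1]),
          class = "lhsurge_parse_error")
  }
  need <- c("participant_id", "cycle_id", "day", "ulh", "creatinine",
            "vlh", "total_protein")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(sprintf("%s is missing required columns: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "lhsurge_parse_error")
  }
  x
}
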