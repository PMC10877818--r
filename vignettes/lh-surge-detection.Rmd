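---
title: "Detecting LH surges and inferring ovulation from daily hormone diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting LH surges and inferring ovulation from daily hormone diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhsurge)
```

## The problem

The fertile window — the five days before ovulation plus the day of
ovulation — is the only part of the menstrual cycle in which intercourse can
lead to conception. Its most practical biomarker is the pre-ovulatory surge
of luteinizing hormone (LH), which rises 16–48 h before ovulation and is
measurable non-invasively in urine. Vaginal discharge (VD), collected
passively on panty liners, is an even less burdensome specimen; if the LH
surge is detectable in VD extract, a sanitary product with a built-in sensor
could replace daily urine testing.

`lhsurge` implements the complete analysis pipeline for evaluating that
idea: limit-of-detection (LOD) handling and concentration normalization of
daily assay values, threshold-based surge detection and ovulation-day
inference on the urinary channel, the same detection on the VD channel, and
a diagnostic evaluation of VD LH (vLH) against urine-derived ovulation
timing. Because per-participant hormone diaries are rarely shareable, the
package also ships a synthetic cohort generator with known ground truth, so
every stage is testable end to end.

## Data model

All data are tidy tibbles. Raw input is one row per participant, cycle and
day with four assay columns: `ulh` (urinary LH, mIU/mL), `creatinine`
(mg/mL), `vlh` (VD-extract LH, mIU/mL) and `total_protein` (mg/mL). Days are
1-based cycle days counted from the first day of menstruation; collection
spans days 10–19 by default. Missing days are empty cells, never imputed.

Concentrations are meaningless without a dilution reference: urine LH is
divided by creatinine (uLH/Cr) and VD-extract LH by total protein (vLH/Pro),
both in mIU per mg of normalizer. All detection operates on these ratios.

## LOD handling

Each assay's LOD is the blank mean plus three standard deviations
(`compute_lod()`; sample SD with the n − 1 denominator, since the convention
is not fixed by the 3σ rule itself — a `sd_type` switch gives the population
form). A measurement strictly below the LOD is replaced by the LOD
(`censor_below_lod()`); a value exactly at the LOD passes, reading "lower
than" literally. When an analyte *and* its normalizer are both below their
LODs on the same day, nothing about that sample is trustworthy and the day
is excluded as a failed collection (`qc_daily_samples()`). Because study
blanks are typically unavailable to re-analysts, LODs are user-supplied
inputs with defaults on the scale of the assay's lowest standard
(0.04 mIU/mL for LH, 0.01 mg/mL for the normalizers).

## The surge-detection rule

For one cycle's normalized series the algorithm (`call_cycle()`) is:

1. **Peak maximum** — the observed day with the largest ratio; ties break to
   the earliest day so calls are deterministic (ties essentially only occur
   in noise-free synthetic data).
2. **Baseline** — the mean ratio over the four days `peak ± 1, peak ± 2`,
   the peak day excluded. At the window edge, or with missing days, the mean
   is over whichever of the four days are observed; at least one is
   required, otherwise the baseline is undetermined and the cycle is
   excluded (`pattern = "none"`) rather than guessed.
3. **Elevated days** — day *d* is part of the surge iff, strictly,

   * value(d) − baseline > 0.30 × (peak value − baseline), **and**
   * value(d) > 2 × baseline.

   "30% of the maximum peak amplitude" is read as 30% of the peak's height
   *above baseline*, applied to each day's own excess, because amplitude
   conventionally means height above baseline and the second condition is
   already baseline-anchored. The alternative reading — 30% of the raw peak
   value — is available via `amplitude_convention = "raw"`.
4. **Morphology** — elevated days are grouped into runs; runs are split only
   by an *observed* non-elevated day (an unobserved gap cannot confirm
   separation). One single-day run is a *sharp single peak*, one longer run
   a *broad single peak*, two or more runs *multiple peaks*; an empty set is
   *no discernible peak* and the cycle is excluded.
5. **Ovulation day** (urine channel) — the day after the last elevated day,
   for every morphology. It may fall one day past the collection window
   (elevated day 19 → ovulation day 20); this is allowed and flagged
   (`ovulation_past_window`). The **fertile window** is the five days before
   ovulation plus ovulation day.
6. **First surge day** (VD channel) — the earliest elevated day, the analogue
   of a first positive home test.

### A structural property of the literal rule

The baseline flanks of a *broad* peak may themselves be elevated, inflating
the baseline. This is not a corner case but a hard constraint: if two
elevated days with excesses $e_i, e_j$ both lie among the four flank days,
condition 2 requires $e_i > 2b + e_j$ and $e_j > 2b + e_i$ simultaneously,
which is impossible for any positive baseline $b$. Consequently a flat
plateau of three or more days can never be fully recovered by the threshold
rule, whatever its height. The rule is implemented literally — no iteration
or baseline re-estimation is invented — and the synthetic generator defaults
to two-day broad peaks, the widest shape the rule can recover exactly. Real
broad surges survive in practice because their shoulders decline, which
keeps most of the run out of the flank window; analysts should be aware
that very wide flat plateaus are structurally uncallable.

## The synthetic cohort generator

`generate_cohort()` draws cycles with known truth so detection and
evaluation can be validated exactly. Defaults emulate the cohort scale the
pipeline targets: 35 participants, 20 contributing two cycles and 15 one
(55 cycles), cycle length a rounded normal with mean 30 and SD 2.4 days
bounded to 25–38, collection on days 10–19.

Per cycle the generator draws a pattern (defaults: sharp 50%, broad 25%,
multiple 25%), a baseline ratio (lognormal, mean 1, CV 0.25) and a surge
amplitude (lognormal, mean 9, CV 0.3). The primary peak sits at
`cycle_length − 15`, clamped into the window, so the implied ovulation day
tracks a 14-day luteal phase. Shapes:

* **sharp** — one elevated day at full amplitude;
* **broad** — `broad_width_days` consecutive days at plateau amplitude with
  a slight (6%) downward taper, so the peak-maximum day is unambiguous even
  under floating-point round-trips, and kept clear of the window end so
  every run day's flanks are observable;
* **multiple** — the primary peak plus `n_extra_peaks` secondary peaks at
  40–80% amplitude placed *before* the primary with at least two clean days
  of separation, matching the empirically common weak-peaks-before-strongest
  morphology and keeping secondary peaks out of the baseline flank window.

Amplitude draws are floored at three times the cycle's baseline. This is
what makes the generator *closed* under the detection rule: at zero noise
and with censoring disabled, every generated urinary series satisfies the
two conditions on exactly its true elevated days, cycle by cycle — the
property the test suite asserts. Physiological LH surges are many-fold
baseline, so the floor does not make the data unrealistic.

The VD channel reuses the cycle's template shifted whole by an integer lag
drawn from a distribution on −4…+4 days (default mode −1, i.e. vLH slightly
ahead of uLH; purely illustrative; no empirical lag distribution is assumed)
and scaled by `vlh_scale = 0.06` onto the vLH/Pro scale, putting surge
values near the 0.1–0.3 mIU/mg range where a diagnostic cutoff is
interesting. Lags can push elevated days outside the collection window;
they are silently truncated, which produces realistic
"no discernible peak" cycles. A shifted run that lands *at* the window edge
can also lose its outer flank days, leaving an elevated neighbour as half
the baseline estimate — such cycles are genuinely uncallable under the
literal rule, so the closure property for the VD channel holds only where
the shifted template keeps clean flanks.

Noise is multiplicative lognormal (default CV 0.2, a plausible inter-day
ELISA figure) because concentrations are positive and assay CVs are
proportional; nothing about the noise model is estimated from real data.
Raw outputs are analyte × normalizer pairs, with creatinine and protein
drawn per day, so the normalization stage is genuinely exercised. Missing
days (default 5%) and per-channel failed collections (default 2%, both
values pushed below LOD) emulate the indignities of home sampling.

What the generator does **not** emulate: endocrine dynamics (no
estrogen/FSH/progesterone feedback), within-run autocorrelated noise,
participant-level amplitude correlations between channels, or anovulatory
cycles with no surge at all. Passing tests therefore demonstrate
correctness of the *pipeline logic* under controlled conditions, not
clinical performance on real diaries.

## Evaluation

`evaluate_cohort()` mirrors a full study analysis:

* **Exclusion funnel** — cycles in total, cycles with a urinary surge, of
  those the cycles with any VD data, of those the cycles with a VD surge.
  Every exclusion is recorded with its reason.
* **Concordance** — per eligible cycle, the offset
  `first_surge_day − ovulation_day` is bucketed at −5…0 (inside the fertile
  window) plus `others`; percentages are integer, rounded half-up (base R's
  banker's rounding would mis-render e.g. 24.5% as 24%).
* **Diagnostics** — one baseline value and one first-surge vLH/Pro value per
  eligible cycle form the negative and positive groups. They are compared
  by a classical pooled-variance Student's t-test (Welch by flag), and by a
  ROC sweep over all observed values, with test-positivity defined as
  value ≥ threshold (home-test semantics). AUC is the trapezoid area, which
  equals the Mann–Whitney exceedance probability; the operating cutoff
  maximizes the Youden index J = sensitivity + specificity − 1, ties broken
  toward the lower cutoff (higher sensitivity, the right bias for a
  fertility test where a missed window is the costlier error). Sensitivity,
  specificity, PPV, NPV and accuracy all derive from the single confusion
  matrix at that cutoff.

Degenerate inputs are handled explicitly rather than left to error: two
constant groups with equal means give t = 0, p = 1; constant groups with
unequal means give an infinite t with a warning; a marker identical in both
groups gives J = 0 at every cutoff with a warning.

## Numerical choices, briefly

* All rule inequalities are strict, matching "greater than".
* Peak ties break earliest; Youden ties break to the lower cutoff.
* Percentages round half away from zero to integers.
* LOD comparisons are strict; equal-to-LOD values are not censored.
* Missing data are excluded, never interpolated.
* Pattern and elevated-day calls are invariant to positive rescaling of a
  series, since both conditions are scale-free ratios.

## Problem sizes

The shipped tests validate the surge rule against a brute-force oracle on
1,000 random 10-day series, the AUC/Youden machinery against exhaustive
oracles on 1,000 random small instances, and ovulation-day recovery on
200-cycle cohorts (exact at zero noise on non-truncated cycles; ≥95% within
±1 day at noise CV 0.1). The acceptance script reruns the full pipeline on
a 55-cycle cohort plus two 200-cycle recovery cohorts, all generated at run
time from a single seed.

## Worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(generator_config(seed = 7))
series <- preprocess_cohort(cohort$samples)
calls  <- call_cohort(series)
ev     <- evaluate_cohort(calls, series)
ev
plot_roc(ev$roc)
```

## Limitations

* The detection rule is the literal threshold procedure: no
  smoothing, no model-based peak fitting, no baseline re-estimation. Its
  broad-plateau blind spot is inherent (see above).
* The fertile window is anchored entirely to the urinary surge; without
  ultrasound ground truth, "ovulation day" here means "day after the last
  elevated uLH day", an operational, not anatomical, definition.
* Generator defaults are illustrative. Conclusions about real VD assays
  require real diaries run through `read_cohort_samples()` →
  `preprocess_cohort()` with assay-specific LODs.
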