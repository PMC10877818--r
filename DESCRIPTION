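Package: lhsurge
Title: Luteinizing Hormone Surge Detection and Ovulation-Day Inference
    from Daily Urine and Vaginal-Discharge Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects luteinizing hormone (LH) surges in daily urinary and
    vaginal-discharge assay series, infers the ovulation day and the six-day
    fertile window, and evaluates vaginal-discharge LH as a diagnostic
    biomarker against urine-derived ovulation timing. Implements
    limit-of-detection censoring by the 3-sigma rule, creatinine and
    total-protein normalization, threshold-based surge calling with
    sharp/broad/multiple peak classification, fertile-window concordance
    tabulation, and ROC analysis with Youden-index cutoff selection. Includes
    a synthetic cohort generator with known ground truth so every stage of
    the pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
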