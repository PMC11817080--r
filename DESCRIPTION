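Package: ptbphewas
Title: Stratified Pre-Conception Diagnosis Associations with Preterm Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A phenome-wide association (PheWAS) pipeline relating maternal
    pre-conception diagnoses to preterm birth, stratified into spontaneous and
    medically indicated deliveries. Maps ICD-9/ICD-10 diagnosis codes to
    truncated phecodes, assigns diagnoses to pregnancies through half-open
    pre-conception exposure windows with a postpartum exclusion period, fits
    per-phecode logistic regressions adjusted for maternal age (natural cubic
    spline), education and insurance, controls the false discovery rate with
    the Benjamini-Hochberg procedure, and screens significant hits with a
    leave-one-carrier-out stability filter. Ships a synthetic electronic
    health record generator with planted effect sizes for end-to-end
    evaluation, plus reporting helpers (Manhattan/forest tables, demographics
    summaries, small-count redaction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
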