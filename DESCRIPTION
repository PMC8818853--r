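Package: mcqamb
Title: Trial-Level Ambivalence in Monetary Choice Questionnaire Delay Discounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and modelling tools for trial-level ambivalence in the
    abbreviated 18-item Monetary Choice Questionnaire (MCQ). Implements
    consistency-based hyperbolic discount-rate (k) estimation, switch-trial
    designation, rescaling of four ambivalence measurement formats to a common
    0-10 scale, switch-centered data preparation with sparse-cell filtering,
    a dual-slopes linear mixed model of ambivalence around the preference
    switch, nested logistic mixed models of choice with reward magnitude and
    delay sensitivities compared by AIC, and a seeded synthetic cohort
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
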