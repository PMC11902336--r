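Package: oxibls
Title: Sleep-Apnea Event Detection and AHI Prediction from Overnight Pulse Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-branch broad-learning pipeline for single-channel SpO2
    oximetry: 30-second windows of the overnight signal are classified as
    apnea/hypopnea (SAS) events while whole-night features drive a parallel
    apnea-hypopnea-index (AHI) regression, the two tasks coupled through a
    global-segment fusion unit that corrects the event-probability sequence
    when the two AHI estimates disagree. Includes a synthetic overnight-SpO2
    generator with annotated desaturation events, subject screening and
    delta-filter preprocessing, per-window and whole-night oximetry feature
    extraction (entropies, desaturation statistics, phase-rectified signal
    averaging, spectral power), a from-scratch broad learning system with
    closed-form ridge output weights and exact incremental refits, and an
    evaluation suite (macro F1, Cohen's kappa, ICC(2,1), Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
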