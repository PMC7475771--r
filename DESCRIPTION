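Package: tmsight
Title: Behavioural Analysis of TMS Masking Experiments on Conscious and
    Unconscious Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-level analysis pipeline for visual masking experiments in
    which transcranial magnetic stimulation (TMS) is applied at early and late
    times relative to a threshold-level stimulus.  Implements non-parametric
    signal detection measures of conscious detection (PrC) and response
    criterion (BrC), residual 'unseen' discrimination capacity (PcU), a
    detection-without-identification measure (PCm), question-specific
    sensitivity and criterion variants, pre-registered exclusion filters
    (same-button strategy, all-negative responding, illogical-response rate,
    above-chance screening of PcU, Chauvenet's outlier criterion, blink
    rejection), sham-normalized early-versus-late temporal contrasts with
    frequentist tests and within-subject standard errors, Bayes factors under
    half-normal, uniform and JZS priors with a sequential stopping rule, and a
    generative synthetic observer for end-to-end validation and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
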