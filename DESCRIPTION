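Package: dra
Title: Automatable Distributed Regression Analysis over a File-and-Trigger
    Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates a distributed data network in which data-partner
    nodes and an analysis-center node jointly fit linear, logistic, and
    site-stratified Cox proportional hazards regression models without any
    patient-level data leaving a partner.  Partners exchange only
    aggregate intermediate statistics (cross-product matrices, score
    vectors, information matrices, log-likelihood values) with the center
    through a folder-based transfer protocol driven by zero-length
    trigger files, with configurable manual, semi-automated, or fully
    automated approval gating.  The distributed estimates are numerically
    equivalent to the corresponding pooled fits.  Includes a synthetic
    cohort generator with known true parameters, distributed
    calibration/discrimination diagnostics from binned aggregates, a
    payload privacy audit, and an end-to-end orchestrator with a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
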