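Package: emstrigger
Title: Trigger-Tool Screening and Validation for Ambulance Mission Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computable implementation of an ambulance trigger tool for
    retrospective record review in the Emergency Medical Services (EMS).
    Encodes a registry of patient-safety triggers (documentation gaps,
    response and on-scene time limits, deviations from treatment guidelines,
    non-conveyance with 72-hour return linkage, medication triggers) as rules
    over structured prehospital mission records, runs the two-stage review
    workflow from NCC MERP severity categories to WHO incident classes
    (near miss, no harm, harmful incident), reproduces the record-selection
    scheme (monthly stratification, seeded Mersenne-Twister sampling), and
    computes the validation statistics used to evaluate such tools:
    per-trigger positive predictive values, item-level content validity
    index, observed agreement, Cohen's kappa and prevalence-adjusted
    bias-adjusted kappa (PABAK). A synthetic-cohort generator with a
    ground-truth manifest and simulated reviewers makes the full pipeline
    testable without access to confidential patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    tidyr,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
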