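Package: fact8d
Title: Valuation and Scoring of the FACT-8D Cancer-Specific Utility Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and applying value sets for the FACT-8D, the
    eight-dimension health-state classification built from nine items of the
    FACT-G cancer quality-of-life questionnaire. Implements the full valuation
    pipeline used in discrete choice experiment (DCE) studies: generation and
    validation of partial-profile choice designs with a survival-duration
    attribute; simulation of quota-sampled respondent cohorts and their choices
    under a random-utility model; representativeness checks and raked (iterative
    proportional fitting) survey weights; the duration-interacted conditional
    logit fitted by maximum likelihood with cluster-robust covariance;
    monotonicity enforcement by iterative level collapsing; conversion of
    coefficients to utility decrements via marginal rates of substitution; and
    scoring of FACT-G item responses to utilities on the QALY scale, including
    the packaged Canadian value set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
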