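Package: pvsignal
Title: Disproportionality-Based Signal Detection for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pharmacovigilance signal detection on individual
    case safety report (ICSR) line listings: proportional reporting
    ratios, reporting odds ratios, and the Bayesian information
    component with credibility bounds, composite signal criteria over
    configurable comparator scopes, standardised MedDRA query (SMQ)
    based event grouping, age-stratified analyses, and chi-square
    factor (risk-cofactor) contingency analysis with post hoc
    residual diagnostics. Includes a calibrated synthetic
    spontaneous-report generator with injectable drug-event relative
    risks for validating every stage of the pipeline, and reference
    summary tables from a published global analysis of
    tramadol-related acute central respiratory depression.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
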