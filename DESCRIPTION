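Package: ppicohort
Title: Chronic Proton Pump Inhibitor Use and Deprescribing Analysis from
    Dispensing Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-utilization studies of chronic proton pump
    inhibitor (PPI) use on longitudinal pharmacy-dispensing claims.
    Implements dose-based temporal-coverage classification of chronic
    users at January 1 anchors (at least 74 dispensed doses, i.e. 80%
    coverage, over the preceding October-December quarter), annual
    incident and prevalent cohort construction, refill-gap
    discontinuation detection with death accounting, treatment-episode
    segmentation under a two-month resumption rule, defined daily dose
    (DDD) accounting, coverage-threshold sensitivity, prescriber
    attribution and across-year trend tests. Ships a seeded synthetic
    claims generator with planted ground truth so the full analysis runs
    without access to confidential claims databases, plus a reproducible
    reporting pipeline and command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
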