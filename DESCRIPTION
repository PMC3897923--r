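Package: tkawait
Title: Markov Cohort Cost-Utility Analysis of Waiting for Total Knee
    Arthroplasty
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A discrete-time Markov cohort engine and decision model for
    the cost-utility analysis of immediate versus delayed total knee
    arthroplasty (TKA) in end-stage knee osteoarthritis.  Provides three
    treatment strategies (immediate TKA, delayed TKA with a non-operative
    treatment bridge, delayed TKA without a bridge), discounted cost and
    QALY accounting under direct-cost and societal (direct plus indirect)
    cost scenarios, incremental cost-effectiveness statistics with
    dominance and net-benefit analysis, deterministic sensitivity and
    threshold analyses, wait-time sweeps, and population-level cost
    projections from user-supplied procedure volumes.  Includes a
    parametric (Gompertz) life-table generator for fully reproducible
    synthetic inputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
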