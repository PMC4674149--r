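Package: tumorpkpd
Title: Gompertz Tumor Growth and Two-Compartment PK/PD Analysis of
    Mouse Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling longitudinal caliper measurements of
    murine skin tumors arising from de novo carcinogenesis. Implements
    ellipsoid volume reconstruction with median-of-three caliper reads,
    Gompertz (and exponential) growth models parametrized by the tumor
    doubling time, a two-compartment pharmacokinetic model of bolus
    5-fluorouracil dosing coupled to a threshold log-kill
    pharmacodynamic term, per-tumor nonlinear least-squares estimation
    of the doubling time and drug kill rate with normalized mean
    squared error goodness of fit, cohort-level statistics
    (within/between-mouse variance decomposition, Spearman correlation,
    two-sample t-test, kernel regression), and a synthetic-cohort
    generator that emulates the study design so every pipeline stage
    can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
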