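Package: murihaz
Title: Age-Specific Mortality Analysis of Sex Differences in Mouse Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Survival analysis toolkit for sex differences in murine
    age-specific mortality. Estimates smoothed mortality hazards from
    censored lifespans with a penalized B-spline Poisson model on binned
    person-time, constructs male:female hazard-ratio curves with bootstrap
    confidence bands, and summarizes their peak and late-life convergence.
    Includes Kaplan-Meier and log-rank comparisons, median-lifespan
    confidence intervals, a maximum-lifespan proportion test, Cox
    proportional-hazards models with sex-by-site interactions, and
    age-stratified regressions of lifespan on bodyweight. A synthetic
    cohort generator with sex-dimorphic Gompertz hazards, cage-level
    censoring, and a shared frailty linking mortality and bodyweight makes
    every stage testable without access to restricted colony data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    splines,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
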