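Package: drcea
Title: Cost-Utility Modelling of Diabetic Retinopathy Screening Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov cohort state-transition model for the cost-utility
    analysis of diabetic retinopathy (DR) screening in diabetic patients,
    comparing no screening with community-based and telemedicine-based
    screening programmes in rural and urban Chinese settings. Provides
    typed, validated parameter sets transcribed from published clinical and
    costing tables; capital-cost annualization and related economic
    conversions; a deterministic cohort engine over health-by-management
    states with age-specific mortality, half-cycle correction and
    discounting; screening-test misclassification and referral cascades;
    incremental cost-utility ratios (ICURs) with dominance classification
    and screening-interval recommendation; one-way deterministic and
    probabilistic sensitivity analysis (beta/gamma parameter distributions,
    percentile bootstrap confidence intervals, cost-effectiveness
    acceptability curves); and an individual-level microsimulation used as
    an independent validation oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
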