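Package: bmigrowth
Title: Allelic Scores and Spline Mixed Models for Childhood Growth
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Longitudinal modelling of childhood body mass index, weight
    and height with semi-parametric linear mixed models on a truncated
    power spline basis and continuous AR(1) within-child residual
    correlation.  Derives the adiposity peak and adiposity rebound per
    child from the fitted individual curves, builds unweighted and
    weighted allelic scores from a fixed 32-SNP adult-BMI panel, tests
    genetic association with whole trajectories and derived milestones,
    and combines results across cohorts by fixed-effect inverse-variance
    and Fisher p-value meta-analysis.  Includes a calibrated two-cohort
    synthetic data generator for validation and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
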