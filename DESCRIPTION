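Package: brainsex
Title: Brain-Sex Continuum Modelling for Longitudinal Adolescent Morphometry
Version: 0.1.0
Authors@R:
    person("Morphometry", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study the development of structural brain sex differences
    across adolescence from regional morphometric volumes. Provides a synthetic
    longitudinal cohort generator with known ground truth, location/scale
    (ComBat-style) multi-site harmonization with empirical-Bayes shrinkage and
    a longitudinal variant, Euler-number quality control, covariate-constrained
    1:1 female-male matching, per-feature intracranial-volume residualization,
    nested cross-validated gradient-boosted sex classifiers yielding a
    male-to-female brain continuum (class probabilities), linear mixed-effects
    association batteries for age, pubertal development, menarche onset and
    mental health with sequential (type I) and marginal (type II) ANOVA, and a
    PCA-based general distress score with baseline-loading projection to
    follow-up.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    nlme,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
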