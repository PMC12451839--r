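Package: braintraj
Title: Group- and Individual-Level Modelling of Adolescent Brain-Volume Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling nonlinear developmental trajectories of brain
    volumes across adolescence from accelerated longitudinal cohorts. Fits
    four-parameter logistic, logarithmic and linear growth curves as nonlinear
    mixed-effects models with covariates on growth parameters, compares them by
    information criteria, gates parameter precision by coefficient of variation,
    and extracts empirical-Bayes individual maturational-timing parameters
    (inflection points, slopes). Includes penalized-spline mixed models (GAMMs)
    with factor-smooth sex interactions for data-driven trajectory shape,
    residual-based longitudinal quality control, a simulator for multi-wave
    accelerated longitudinal designs with known ground truth, and a per-region
    analysis pipeline with forward-stepwise covariate selection and sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
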