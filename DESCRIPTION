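Package: prevalca
Title: Bayesian Latent Class Estimation of Disease Prevalence from
    Imperfect Diagnostic Ascertainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates true disease prevalence when case ascertainment is
    imperfect, as is typical for diagnoses recorded in administrative
    claims databases. Provides the closed-form Rogan-Gladen
    misclassification correction, conjugate data-augmentation Gibbs
    samplers for the non-identifiable single-test model and the
    identifiable multi-test conditional-independence latent class model,
    an EM maximum-likelihood fitter, a hierarchical Bayesian extension
    for multi-region prevalence with partial pooling, and a synthetic
    panel generator so every estimator is testable without access to
    real registry data. Includes CSV/JSON input and output for
    cross-classified test-pattern counts and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
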