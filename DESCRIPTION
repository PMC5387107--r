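Package: modelspace
Title: Personalized Treatment-Response Prediction by Learning in the Model Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalized prediction of medication response over a dose-titration
    course using conjugate Bayesian linear regression in a "learning in the model
    space" framework. Each patient is represented by a Normal-Inverse-Gamma
    posterior over a subject-specific response vector; virtual patient profiles
    for new patients are constructed from a pool of fitted patient models either
    by a pseudo-inverse linear mapping from baseline latent factors or by
    Gaussian-kernel weighted model averaging. Supports appointment-independent,
    incremental-regression and incremental-update prediction strategies,
    patient-coherent k-fold cross-validation, Student-t posterior predictive
    intervals, and uncertainty-aware dichotomous remission classification with
    ROC/balanced-accuracy evaluation. Includes a seeded synthetic titration
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    pracma,
    withr
Config/testthat/edition: 3
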