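Package: learnsim
Title: Synthetic Clinical Cohorts with Hierarchical Learning-Curve Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic patient-level datasets for benchmarking
    post-market treatment-safety surveillance methods. Patients with
    correlated, non-normal clinical features are produced by an iterative
    rank-substitution algorithm, nested within providers and institutions,
    assigned a novel or reference treatment from a calibrated logistic
    model, and given adverse outcomes that combine intrinsic patient and
    treatment risk with provider- and institution-level experiential
    learning curves of known form, magnitude, and speed. Ground truth
    (latent probabilities and case-series indices) is emitted alongside
    the public dataset, and an evaluation harness checks that realized
    prevalences, event rates, odds ratios, and learning signatures match
    their specifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    mgcv,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
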