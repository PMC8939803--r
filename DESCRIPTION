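Package: plateletABC
Title: Stochastic Platelet Deposition Modelling and Likelihood-Free
    Inference for Platelet-Function Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-simulates platelet adhesion and aggregation in a
    cone-and-plate (Impact-R type) shear device with a stochastic
    particle model, and estimates its seven biologically meaningful
    parameters per subject by approximate Bayesian computation (ABC)
    with discriminative summary statistics learned by large-margin
    metric learning. Includes a synthetic cohort generator, kernel
    density MAP estimation, rank-based group testing with false
    discovery rate control, a nearest-median pathology classifier, and
    posterior predictive checks scored by the energy score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
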