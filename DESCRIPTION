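Package: spatlogit
Title: Bayesian Random-Parameters Spatial Logistic Models for Crash Fatality Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits Bayesian logistic regression models for binary crash
    fatality outcomes on segmented roadway networks, with optional spatially
    structured section effects under a Leroux conditional autoregressive
    (CAR) prior and optional crash-level random (heterogeneous) coefficients.
    Estimation is by adaptive Metropolis-within-Gibbs MCMC with diffuse
    priors; reporting covers posterior summaries with credible-interval
    significance flags, odds ratios, average marginal effects, heterogeneity
    shares for random coefficients, and DIC-based model comparison. Includes
    a synthetic crash-data generator with known truth for parameter-recovery
    studies, plain-text data I/O with strict schema validation, and roadway
    segmentation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
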