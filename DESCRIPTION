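Package: admixabc
Title: Approximate Bayesian Computation for Three-Population Divergence
    with Admixture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation-based (ABC) model selection and parameter
    estimation for histories of three-population divergence with
    admixture, from unphased and unpolarized multi-locus sequence data.
    Includes a structured-coalescent simulator for seven candidate
    demographic models (continuous-window or pulse admixture), moment
    compression of Wakeley-Hey site-category summary statistics,
    rejection sampling, multinomial-logistic model choice,
    neural-network regression-adjusted posteriors, pseudo-observed
    dataset (PODS) cross-validation, and PCA-based prior- and
    posterior-predictive model checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
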