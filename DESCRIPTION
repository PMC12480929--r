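Package: priorelicit
Title: Elicitation and Evaluation of Gaussian Priors for Bayesian Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Structured elicitation of Gaussian prior distributions for the
    coefficients of logistic and linear regression models from large language
    models, and evaluation of how well the elicited prior sets agree with
    observed data. Provides a prompt builder with a machine-readable response
    schema and a deterministic replay transport for recorded transcripts;
    maximum-likelihood fits with Gaussian approximations of the estimator's
    sampling distribution (asymptotic or bootstrap); Laplace and conjugate
    Gaussian posterior approximations; closed-form Kullback-Leibler
    prior-data agreement scores aggregated into ranked tables; prior
    predictive checks; and cross-validated predictive comparison of prior
    sets with Nadeau-Bengio corrected t-tests and Benjamini-Hochberg
    multiplicity adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
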