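Package: cvlpa
Title: Latent Profile Phenotyping of Cardiovascular Risk with Cognitive
    Distal Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Gaussian latent profile (finite mixture) models to
    continuous vascular-disease risk indicators by maximum likelihood via
    the EM algorithm, with full-information handling of missing cells and
    optional concomitant (multinomial-logistic) covariates predicting class
    membership. Provides class enumeration via BIC, relative entropy and a
    parametric bootstrap likelihood-ratio test; a bi-factor confirmatory
    factor model for cognitive test batteries with CFI/TLI/RMSEA/BIC fit
    indices and regression factor scores; Wald tests and posterior-probability
    regressions of distal outcomes on latent classes; random-forest
    cross-validation of class solutions; Framingham point scoring for women;
    and a calibrated synthetic cohort generator emulating the baseline
    structure of a multisite menopausal cohort study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
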