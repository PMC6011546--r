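Package: BayesFeedEff
Title: Bayesian Multi-Trait Genetic Evaluation of Feed Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pedigree-based trivariate animal model for average daily feed
    intake, average daily gain and lean meat percentage in pigs, fitted by
    Gibbs sampling with inverse-Wishart covariance updates. From the posterior
    chain the package derives breeding values and (co)variances for linear
    (residual feed intake, phenotypic and genetic definitions) and ratio
    (feed conversion ratio) efficiency traits, genetic trends, the genetic
    (co)variance available for selection, and posterior distributions of
    direct and correlated responses to truncation selection. Includes a
    pedigreed-population simulator with multi-generation selection so the
    whole pipeline can be exercised without proprietary data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
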