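Package: bootlda
Title: Unbiased Convex Bootstrap Error Estimation for Linear Discriminant
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finite-sample calibration of the convex (0.632-type) bootstrap
    error estimator for linear discriminant analysis of two Gaussian
    populations. Computes exact expected true, resubstitution, and zero
    bootstrap error rates of the LDA classifier with known covariance, in the
    univariate heteroskedastic and multivariate homoskedastic cases, using
    bivariate normal probabilities and the Imhof-Pearson three-moment
    approximation to doubly noncentral F tail probabilities. From these
    moments it derives the convex-combination weight that makes the bootstrap
    error estimator unbiased, generates weight lookup tables over Bayes error
    and sample size, and provides the empirical estimators (resubstitution,
    zero bootstrap, convex and 0.632 bootstrap) together with a simulation
    harness that verifies unbiasedness on synthetic Gaussian data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
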