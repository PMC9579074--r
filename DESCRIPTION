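Package: semlrt
Title: Corrected Likelihood-Ratio Test Statistics for Covariance Structure
    Models under Non-Normality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the finite-sample behaviour of corrections to the
    likelihood-ratio model test statistic in structural equation modeling when
    the observed variables are non-normal. Provides a confirmatory factor
    analysis engine based on normal-theory maximum likelihood, the
    Satorra-Bentler scaled statistic with and without Bartlett correction,
    mean-and-variance adjusted and scale-shifted statistics, a third-moment
    adjusted statistic, inference from the asymptotic weighted chi-square
    mixture distribution, robust RMSEA and CFI variants, a multivariate
    non-normal data generator that controls whether non-normality originates
    in the correlated (latent) components, the independent (error) components,
    or the marginals directly, and a Monte Carlo harness for type I error and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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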