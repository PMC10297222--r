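Package: odinar
Title: Observation-Driven Random-Coefficient INAR(1) Models with Poisson
    Thinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference for first-order integer-valued
    autoregressive (INAR(1)) count time series built on the Poisson
    thinning operator, where the thinning intensity is driven by the
    previous observation through a logistic link and may itself be random
    (fixed, uniform, exponential or chi-square conditional distributions).
    Provides conditional least squares estimation with sandwich
    asymptotics, conditional maximum likelihood under the four
    coefficient-distribution families, chi-square interval estimation
    based on the estimating functions, profile empirical-likelihood tests,
    AIC/BIC model comparison, a seeded simulator, and a Monte-Carlo study
    harness for estimator quality, interval coverage and test size/power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
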