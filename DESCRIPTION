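Package: quadexp
Title: The Two-Parameter Quadratic Exponential Lifetime Distribution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Density, distribution, quantile, hazard and random generation
    for the two-parameter quadratic exponential distribution, a gamma
    mixture with density proportional to (alpha + beta*x + x^2)*exp(-beta*x)
    on the positive half-line.  Provides closed-form moments and derived
    actuarial and reliability measures (mean residual life, Lorenz and
    Bonferroni curves, Renyi entropy, fuzzy reliability, value at risk,
    tail value at risk, tail variance, mean excess, limited expected
    value), fifteen frequentist estimation methods (maximum likelihood,
    maximum product of spacings, and a family of minimum-distance and
    spacings-based criteria), a Monte Carlo engine that benchmarks and
    ranks the estimators, and a goodness-of-fit suite that compares the
    distribution against common one- and two-parameter lifetime models
    with KS, Cramer-von Mises and Anderson-Darling statistics and
    asymptotic p-values.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
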