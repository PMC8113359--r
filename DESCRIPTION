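Package: agesel
Title: Age-Dependent Selection on Gene Expression and Molecular Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to relate the age at which a gene is expressed to the
    strength of natural selection acting on it. Computes per-gene
    age-of-expression statistics (the regression of log expression on age,
    tissue specificity, age-of-maximum expression), polymorphism and
    divergence summaries (pN/pS, dN/dS, the early/late contrast statistic),
    estimates per-gene scaled selection coefficients and the beneficial
    fraction of new mutations by numerically inverting a Poisson random
    field model of segregating and fixed sites, evaluates a gambler's-ruin
    random-walk model of gene lifespan, and provides the regression and
    rank-based association layer together with a synthetic cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
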