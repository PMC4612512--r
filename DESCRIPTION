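Package: sibvar
Title: Quantitative-Genetic Analysis of Half-Sib Breeding Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of additive genetic variance, narrow-sense
    heritability and mean-standardized evolvability from nested
    full-sib/half-sib breeding designs, with from-scratch restricted
    maximum likelihood (REML) for the sire/dam nested linear mixed model,
    Wald and likelihood-ratio tests, delete-one-sire-family jackknife
    standard errors, pedigree-based univariate and bivariate animal
    models for genetic correlations, and a synthetic breeding-design
    generator with known true genetic architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
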