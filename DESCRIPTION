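Package: matchedlasso
Title: Sparse Conditional Logistic Regression for Matched Case-Control and
    Case-Crossover Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: L1-penalized (Lasso) conditional logistic regression for
    individually matched 1:1 and 1:M case-control and case-crossover studies.
    The conditional likelihood is rewritten in terms of within-stratum
    covariate differences, which makes the iteratively reweighted least
    squares (IRLS) weight matrix diagonal; each reweighted Lasso problem is
    solved by cyclic coordinate descent on the p x p Gram system, so memory
    scales with the number of predictors rather than the number of subjects.
    Includes regularization-path computation with warm starts, likelihood-based
    K-fold cross-validation and BIC model selection, forced (unpenalized)
    confounders, a simulator for matched and case-crossover designs with known
    sparse effects, and broom-style tidiers plus ggplot2 path and
    cross-validation plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
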