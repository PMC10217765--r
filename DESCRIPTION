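Package: midecomp
Title: Mutual Information Decomposition for Contingency Table Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orthogonal mutual-information (MI) decomposition of multi-way
    contingency tables on the likelihood-ratio (G-squared) scale: chain-rule
    MI/CMI identities with degrees of freedom and chi-square p-values, the
    Pythagorean split of a conditional MI term into an interaction
    (heterogeneous-association) and a partial-association component with the
    corresponding two-step likelihood-ratio test, iterative proportional
    fitting of hierarchical log-linear models, MI-ratio forward selection with
    backward deletion of dispensable predictors, identity rearrangement, and
    construction of parsimonious log-linear and grouped-binomial logistic
    models for categorical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    withr
Suggests:
    caret,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
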