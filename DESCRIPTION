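Package: rrvwm
Title: Resource-Rational Models of Set Size Effects in Visual Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resource-rational modelling of visual working memory.
    Encoding precision is quantified as Fisher information of a Von Mises
    error distribution with gamma-distributed trial-to-trial variability,
    and the amount of resource invested per item is chosen to minimize an
    expected behavioral cost plus a linear neural cost weighted by lambda.
    The package provides the circular probability machinery, a family of
    behavioral cost functions, the per-item resource optimizer with its
    encode-nothing and unbounded-encoding regime thresholds, alternative
    allocation policies (power law, fixed resource, proportional, and
    constrained-optimal splits), maximum-likelihood fitting of trial-level
    delayed-estimation data with AIC and interleaved five-fold
    cross-validation, a synthetic-data generator emulating nine published
    experimental designs, and a Bayesian-observer analysis of whole-display
    change detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
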