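Package: wmreport
Title: Mixture Models for Whole-Report Continuous-Reproduction Working-Memory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-report continuous-reproduction tests of
    visual working memory, in which participants reproduce the circular feature
    (e.g., color on a 360-degree wheel) of every item in a memory array in a
    self-chosen order. Provides circular error computation, von Mises mixture
    measurement models (two- and three-parameter), per-participant
    maximum-likelihood fits with BIC comparison against a pure-guessing uniform
    model, hierarchical Bayesian estimation of population-level mixture
    parameters with posterior modes and highest-density intervals, and a
    hierarchical double-mixture model (HDMM) with a participant-level latent
    indicator separating consistent guessers from mixture-model responders.
    Includes a generative simulator of free-order whole-report experiments for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite
Config/testthat/edition: 3
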