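Package: edabisect
Title: Ensemble-Distribution Modeling of Temporal Bisection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the statistics of a duration set shape
    temporal bisection. Simulates trial-level bisection experiments over
    arbitrary duration distributions, estimates points of subjective equality
    (PSE) and just-noticeable differences (JND) by maximum-likelihood
    cumulative-Gaussian fitting, fits a family of hierarchical Bayesian
    decision models -- from a simple midpoint reference to an
    ensemble-distribution account in which the bisection reference tracks the
    ensemble mean and decision sensitivity scales with the ensemble
    mean-to-spread ratio -- and compares models by WAIC and by the Euclidean
    distance between predicted and observed PSE-JND pairs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    rjags,
    coda,
    jsonlite,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
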