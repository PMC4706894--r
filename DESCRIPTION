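Package: choqfuse
Title: Choquet-Integral Fusion of Classifier Ensembles with Abstention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines measurement-level outputs of heterogeneous classifiers
    with the Choquet integral with respect to fuzzy measures (capacities)
    represented by their Moebius transform. Capacities are identified from
    training data by constrained least squares (a convex quadratic program
    with monotonicity and normalization constraints), class-specific
    ensembles are built greedily from Shapley values and extended
    interaction indices, and decisions may abstain when the top two class
    likelihoods are too close. Includes evaluation metrics for
    brain-computer interfaces (copy-spelling efficiency with a
    not-defined convention, and Nykopp's information transfer rate via
    Blahut-Arimoto channel-capacity iteration) and a synthetic generator
    of correlated measurement-level classifier scores emulating first-level
    P300 speller classifiers.
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
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
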