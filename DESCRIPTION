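Package: ipdsim
Title: Iterated Prisoner's Dilemma Tournaments and Winner-Feature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates Iterated Prisoner's Dilemma round-robin tournaments of
    four kinds (standard, noisy, probabilistic ending, and noisy probabilistic
    ending) over a catalog of precisely specified canonical strategies, and
    analyses which behavioral features distinguish tournament winners. Provides
    a single-match engine with action noise and geometrically distributed match
    lengths, per-strategy tournament summaries (cooperation rating, state
    occupancies, conditional cooperation rates), derived features such as the
    normalized rank and the least-squares distance of a strategy's memory-one
    behavior to the zero-determinant family (SSE), a randomized trial sampler
    for tournament campaigns, Spearman correlation and multivariate regression
    of features against performance, winner-feature distributions, and a
    synthetic feature-table generator with planted effects for validating the
    statistical layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
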