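Package: hivecrit
Title: Criticality Analysis of Collective Activity via Ising Models and Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting signatures of critical dynamics in the
    collective activity of animal groups, built around the comparison of
    empirical movement data with the two-dimensional Ising model. Provides
    trajectory preprocessing (uniform resampling, inactivity filtering,
    kinetic-energy transforms), a Metropolis Monte Carlo simulator for the
    Ising model on a torus, Pearson correlation networks matched on mean
    degree, maximum-likelihood fitting of heavy-tailed degree distributions
    (power law, power law with exponential cutoff, log-normal) with
    likelihood-ratio model comparison, small-world metrics against
    Erdos-Renyi reference ensembles, Hurst-exponent estimation from
    lag-variance scaling with shuffle controls, and synthetic generators
    (fractional Gaussian noise, hive-like trajectory data) for end-to-end
    validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
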