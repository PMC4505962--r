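Package: netmatch
Title: Preferential Attachment as Probability Matching in Growing Social Networks
Version: 0.9.0
Authors@R: person("Net", "Match", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Models newcomers joining a social network as softmax
    (Luce-choice) decision makers whose sensitivity to popularity is a
    real-valued exponent L. Provides a growing-network simulator with
    fixed or Gaussian-distributed per-newcomer L, Bayesian estimation of
    L from two-choice behavioral data (per-participant, per-choice,
    shared, and hierarchical individual-differences models fit by
    Metropolis-Hastings with Gelman-Rubin diagnostics and AICc model
    comparison), small-world connectivity metrics (degree distribution,
    characteristic path length, mean local clustering), bootstrap
    correlation statistics for trait analyses, a synthetic-cohort
    generator emulating the behavioral dataset, and a command-line
    driver for parameter sweeps over population heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
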