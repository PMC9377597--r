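Package: beliefsim
Title: Belief-Updating Models, Model Comparison and Individual-Difference
    Statistics for Probability-Report Tasks
Version: 0.1.0
Authors@R:
    person("Belief", "Sim", email = "maintainer@beliefsim.org", role = c("aut", "cre"))
Description: Tools for modelling trial-by-trial belief updating in tasks where
    participants repeatedly report a subjective probability while receiving
    binary feedback. Beliefs are represented as Beta distributions and each
    report is treated as a single sample from the current belief distribution.
    Four belief-updating models (Bayesian and Rescorla-Wagner dynamics, each
    with and without a valence bias) are fitted per participant by maximum a
    posteriori estimation under bounded priors, and compared at the population
    level with random-effects exceedance probabilities. The package also ships
    a synthetic cohort generator that plants a configurable individual-
    difference structure (latent internalizing factors, confirmation bias,
    profile popularity), Anderson-Rubin factor scoring from a fixed bifactor
    loadings matrix, and the downstream statistics: exclusion filters,
    permutation-based correlation tests with Benjamini-Hochberg correction,
    joint regressions with coefficient-difference permutation tests, and
    bootstrap linear mediation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
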