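Package: rlddm
Title: Reinforcement-Learning Drift-Diffusion Modelling of Probabilistic
    Selection Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and hierarchical Bayesian analysis of stereotype-based
    associative learning in the probabilistic selection task (PST).  Provides
    the PST task structure (80/70/60 percent reward pairs with blockwise
    accuracy-criterion termination), a Wiener first-passage-time likelihood
    with small- and large-time series expansions, a reinforcement-learning
    drift-diffusion model (RL-DDM) in which delta-rule expected values set
    trial-wise drift rates, synthetic cohort generation with known ground
    truth, adaptive MCMC estimation of the hierarchical model with
    Gelman-Rubin diagnostics and DIC model comparison, posterior predictive
    checks, and directional posterior tests with complementary posterior
    odds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
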