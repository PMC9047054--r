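Package: fluidrl
Title: Offline Reinforcement Learning for ICU Fluid-Balance Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns and evaluates fluid-balance treatment policies for ICU
    sepsis cohorts from logged clinical time series. Provides a synthetic
    cohort generator with known latent severity and behavior propensities,
    clinical preprocessing (outlier rules, 6-hour block aggregation,
    forward-fill and k-nearest-neighbour imputation, quintile action
    discretization, terminal survival rewards), on-policy SARSA and double
    deep Q-network (DDQN) learners over a shared 25-128-128-5 Q-network,
    off-policy evaluation by inverse propensity scoring, a direct outcome
    model, and the doubly-robust estimator, plus mortality-concordance
    analyses of predicted versus observed fluid strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
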