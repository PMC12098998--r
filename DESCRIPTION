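Package: avoidprior
Title: Cognitive Models of Active Avoidance Under Prior Beliefs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative task designs, choice models and model-comparison
    machinery for two-task active-avoidance experiments in which agents
    decide whether to pay a cost to avert a probabilistic loss. Implements
    a beta-Bernoulli Bayesian learner alongside softmax-only, win-stay
    lose-shift and static-probability baselines, action-bias (lapse)
    augmentations, and joint cross-task variants with shared or separate
    priors. Provides seeded task-schedule generation, agent simulation,
    subject-level MAP estimation with Laplace model evidence, an
    empirical-Bayes group refinement, random-effects Bayesian model
    selection with protected exceedance probabilities, model- and
    parameter-recovery harnesses, and reliability statistics (ICC(2,1),
    Spearman correlation with permutation tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
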