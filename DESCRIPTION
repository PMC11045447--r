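Package: choicebias
Title: Dataset Bias and Structured Decision Noise in Models of Human Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dataset bias between laboratory and online
    collections of human binary risky choices. Provides readers for the
    CPC15/CPC18/choices13k gamble formats, a BEAST agent-based choice
    simulator, naive, psychological and higher-order stochastic-dominance
    features of gamble pairs, reference choice models (sparse multilayer
    perceptron with sparse evolutionary training, context network, random
    forest, support vector machine), a transfer-testing harness, a hybrid
    generative decision-noise model (random guessing plus log-odds rescaling)
    with MCMC posterior inference over its two parameters, additive feature
    attribution (Shapley values), and a synthetic-data generator that makes
    the whole pipeline reproducible without the original datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    rjags,
    coda,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
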