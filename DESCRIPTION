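Package: coopeq
Type: Package
Title: Quantal Response and Markov-Strategy Equilibria for Cooperation
    Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of cooperation in iterated Prisoner's Dilemma and Trust
    Game laboratory sessions. Implements the logit quantal-response equilibrium
    (QRE) of the one-shot Prisoner's Dilemma with its closed-form inversion
    from observed cooperation rates, the QRE of the sequential Trust Game with
    precision-parameter fitting to observed trust and gratefulness, and the
    stationary model of the iterated Prisoner's Dilemma in memory-one (Markov)
    strategies, including the symmetric totally mixed Nash equilibrium curve,
    signed tolerance distances, and epsilon-equilibrium payoff-deviation
    statistics. Ships the published session-summary tables as fixtures,
    estimators of the memory-one parameters from round-level session logs, and
    seeded simulators of the experimental design (random re-pairing and fixed
    small groups) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
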