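Package: crdelegate
Title: Delegation Errors in the Collective-Risk Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary game-theoretic model of delegation to autonomous
    agents in the collective-risk dilemma. Delegation is distinguished from
    direct play solely by the timing of mistakes: per-round execution errors
    for direct play versus one-shot program or delegate-selection errors for
    delegation. The package simulates the threshold public-goods game over
    memory-1 behavioral profiles, estimates pairwise payoff tables by Monte
    Carlo, computes pairwise Fermi fixation probabilities and the
    small-mutation-limit stationary distribution over monomorphic states, and
    derives population-level success rates, public-account contributions and
    delegation rates as functions of the error probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
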