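# tiny, exhaustively enumerable game: 2 players, 2 rounds, threshold 8
tiny_config <- function() {
  crd_config(N = 2, E = 8, r = 2, actions = c(0, 2, 4), p = 0.9, threshold = 8)
}

# hand-made pairwise payoff table (for evolution-layer tests)
fake_table <- function(pi_a, pi_b) {
  crdelegate:::new_pair_table(seq_along(pi_a) - 1, pi_a, pi_b,
                              NULL, NULL, 0, 1L, 1)
}

six_of <- function(profile, mode = "none") {
  rep(list(strategy_spec(profile, mode)), 6)
}

triad_labels <- function(mode) {
  paste0(c("reciprocal", "always-2", "compensatory"), " (", mode, ")")
}
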