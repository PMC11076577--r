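new_pair_table <- function(j, pi_a, pi_b, a, b, epsilon, nsim, seed) {
  out <- tibble::tibble(j = j, pi_a = pi_a, pi_b = pi_b)
  structure(out, class = c("pair_payoff_table", class(out)),
            strategy_a = a, strategy_b = b, epsilon = epsilon,
            nsim = nsim, seed = seed)
}

# reflect a table so that the roles of A and B swap:
# pi_a'[j] = pi_b[N-1-j], pi_b'[j] = pi_a[N-1-j]
reflect_pair_table <- function(tab) {
  n <- nrow(tab)
  new_pair_table(tab$j, rev(tab$pi_b), rev(tab$pi_a),
                 attr(tab, "strategy_b"), attr(tab, "strategy_a"),
                 attr(tab, "epsilon"), attr(tab, "nsim"), attr(tab, "seed"))
}

#' Estimate pairwise payoff tables by Monte Carlo
#'
#' For every group composition of `j + 1` A-players and `N - 1 - j` B-players
#' (plus the two monomorphic compositions), `nsim` independent games are
#' simulated with fresh error realizations and payoffs are averaged within
#' each strategy. `pi_a[j]` is the expected payoff of an A-player with `j`
#' A-co-players; `pi_b[j]` that of a B-player in a group containing `j`
#' A-players. Each composition runs on a deterministic child stream derived
#' from `seed` and a canonical (order-insensitive) pair key, so the table is
#' reproducible and `estimate_pair_payoffs(b, a)` is the exact reflection of
#' `estimate_pair_payoffs(a, b)`.
#'
#' @param a,b [strategy_spec()] objects.
#' @param config A [crd_config()].
#' @param epsilon Error probability.
#' @param nsim Simulated games per composition.
#' @param seed Integer base seed.
#' @return A `pair_payoff_table` tibble with columns `j`, `pi_a`, `pi_b`
#'   (rows `j = 0 .. N-1`) and metadata attributes.
#' @export
estimate_pair_payoffs <- function(a, b, config = crd_config(), epsilon = 0,
                                  nsim = 10000, seed = NULL) {
  stopifnot(inherits(a, "crd_strategy"), inherits(b, "crd_strategy"),
            epsilon >= 0, epsilon <= 1, nsim >= 1)
  if (is.null(seed)) seed <- new_seed()
  ka <- spec_key(a)
  kb <- spec_key(b)
  swap <- ka > kb
  first <- if (swap) b else a
  second <- if (swap) a else b
  child <- key_seed(seed, paste(min(ka, kb), max(ka, kb), sep = "&"))
  ea <- engine_args(list(first, second), config)
  out <- crd_pair_table(ea$profiles[1, ], ea$modes[1], ea$profiles[2, ],
                        ea$modes[2], config$actions, config$N, config$E,
                        config$r, config$p, config$threshold, epsilon,
                        ea$pool, ea$pool_index[1], ea$pool_index[2],
                        as.integer(nsim), as.numeric(child))
  tab <- new_pair_table(0:(config$N - 1), out$pi_a, out$pi_b,
                        first, second, epsilon, nsim, seed)
  if (swap) reflect_pair_table(tab) else tab
}

#' Payoff tables for every pair in a strategy roster
#'
#' Computes [estimate_pair_payoffs()] once per unordered roster pair and
#' stores both orientations, the input required by [fixation_matrix()] and
#' [sml_stationary()].
#'
#' @param roster List of distinct [strategy_spec()] objects (length `S >= 2`).
#' @inheritParams estimate_pair_payoffs
#' @return An object of class `pair_table_set`: an `S x S` list matrix whose
#'   `[i, j]` entry is the pair table with strategy `i` in the A role.
#' @export
pair_payoff_tables <- function(roster, config = crd_config(), epsilon = 0,
                               nsim = 10000, seed = NULL) {
  S <- length(roster)
  stopifnot(S >= 2)
  if (is.null(seed)) seed <- new_seed()
  keys <- vapply(roster, spec_key, character(1))
  if (anyDuplicated(keys)) {
    stop("roster strategies must be pairwise distinct (profile + error mode)")
  }
  tabs <- vector("list", S * S)
  dim(tabs) <- c(S, S)
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      tab <- estimate_pair_payoffs(roster[[i]], roster[[j]], config, epsilon,
                                   nsim, seed)
      tabs[[i, j]] <- tab
      tabs[[j, i]] <- reflect_pair_table(tab)
    }
  }
  structure(tabs, class = "pair_table_set", roster = roster,
            epsilon = epsilon, nsim = nsim, seed = seed, config = config)
}
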