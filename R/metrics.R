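#' Success probability and expected contributions of a monomorphic group
#'
#' Simulates `nsim` games of `N` copies of one strategy: `eta` is the
#' fraction of games reaching the threshold, `C` the mean total public
#' account. These per-strategy quantities are the building blocks of the
#' population-level averages (the small-mutation limit keeps the population
#' monomorphic almost always).
#'
#' @param spec A [strategy_spec()].
#' @param config A [crd_config()].
#' @param epsilon Error probability.
#' @param nsim Number of simulated games.
#' @param seed Integer seed.
#' @return A tibble row of class `monomorphic_metrics`: `label`, `mode`,
#'   `eta`, `C`, `mean_payoff`, `epsilon`, `nsim`, `seed`.
#' @export
monomorphic_metrics <- function(spec, config = crd_config(), epsilon = 0,
                                nsim = 10000, seed = NULL) {
  stopifnot(inherits(spec, "crd_strategy"), nsim >= 1)
  if (is.null(seed)) seed <- new_seed()
  child <- key_seed(seed, paste0("mono:", spec_key(spec)))
  g <- play_game(rep(list(spec), config$N), config, epsilon, nsim, child)
  out <- tibble::tibble(label = spec$label, mode = spec$mode,
                        eta = mean(g$success), C = mean(g$public_account),
                        mean_payoff = mean(g$payoffs),
                        epsilon = epsilon, nsim = nsim, seed = seed)
  class(out) <- c("monomorphic_metrics", class(out))
  out
}

check_sigma <- function(sigma, n) {
  stopifnot(length(sigma) == n, all(sigma >= 0))
  if (abs(sum(sigma) - 1) > 1e-8) stop("`sigma` must be normalized")
  invisible(sigma)
}

#' Population average success rate
#'
#' Stationary-distribution-weighted mean of the per-strategy monomorphic
#' success probabilities: `eta_bar = sum_i sigma_i * eta_i`.
#'
#' @param sigma Normalized stationary distribution over the roster.
#' @param eta Per-strategy monomorphic success probabilities, same length.
#' @return Scalar in `[0, 1]`.
#' @export
success_rate <- function(sigma, eta) {
  check_sigma(sigma, length(eta))
  sum(sigma * eta)
}

#' Population average public account
#'
#' Stationary-distribution-weighted mean of the per-strategy monomorphic
#' group contributions: `C_bar = sum_i sigma_i * C_i`.
#'
#' @param sigma Normalized stationary distribution over the roster.
#' @param C Per-strategy monomorphic mean public accounts, same length.
#' @return Scalar in `[0, N * r * max(A)]`.
#' @export
avg_public_account <- function(sigma, C) {
  check_sigma(sigma, length(C))
  sum(sigma * C)
}

#' Population delegation rate
#'
#' Total stationary mass on delegation strategies (error mode `program` or
#' `delegate`): `d_bar = sum_{s in S_del} sigma_s`.
#'
#' @param sigma Normalized stationary distribution over the roster.
#' @param roster List of [strategy_spec()] objects aligned with `sigma`.
#' @return Scalar in `[0, 1]`, or `NA` (with a warning) when the roster
#'   contains no delegation strategy.
#' @export
delegation_rate <- function(sigma, roster) {
  check_sigma(sigma, length(roster))
  del <- vapply(roster, function(s) s$mode %in% c("program", "delegate"),
                logical(1))
  if (!any(del)) {
    warning("roster contains no delegation-mode strategy; delegation rate ",
            "is undefined")
    return(NA_real_)
  }
  sum(sigma[del])
}

#' Actual per-round error rate of a strategy
#'
#' Empirical per-round probability that the emitted action differs from the
#' action the intended profile would have taken in the same (realized) game
#' state, estimated over monomorphic games; rounds after the threshold stop
#' are excluded. For execution errors this equals `epsilon` by construction;
#' for one-shot program/delegate errors it can deviate substantially, since
#' a mis-realized profile may coincide with -- or diverge from -- the
#' intended one depending on the context it encounters.
#'
#' @inheritParams monomorphic_metrics
#' @return Scalar deviation frequency in `[0, 1]`.
#' @export
actual_error_rate <- function(spec, config = crd_config(), epsilon = 0,
                              nsim = 10000, seed = NULL) {
  stopifnot(inherits(spec, "crd_strategy"), nsim >= 1)
  if (is.null(seed)) seed <- new_seed()
  ea <- engine_args(rep(list(spec), config$N), config)
  out <- crd_sim_games(ea$profiles, ea$modes, config$actions, config$E,
                       config$r, config$p, config$threshold, epsilon,
                       ea$pool, ea$pool_index, as.integer(nsim),
                       as.numeric(seed), TRUE)
  out$deviation_rate
}

#' Population-level metrics at one error probability
#'
#' Runs the full pipeline for one roster and one `epsilon`: pairwise payoff
#' tables, small-mutation-limit stationary distribution, monomorphic metrics
#' per strategy, and the weighted population averages.
#'
#' @param roster List of [strategy_spec()] objects (or a kind accepted by
#'   [build_population()]).
#' @param config A [crd_config()].
#' @param evo An [evolution_config()].
#' @param epsilon Error probability.
#' @param nsim Simulated games per group composition (payoffs) and per
#'   monomorphic estimate.
#' @param seed Integer seed.
#' @return A list of class `population_metrics`: `summary` (one-row tibble
#'   with `epsilon`, `success_rate`, `avg_public_account`,
#'   `delegation_rate`), `strategies` (per-strategy tibble with `sigma`,
#'   `eta`, `C`), and the `stationary_result`.
#' @export
population_metrics <- function(roster, config = crd_config(),
                               evo = evolution_config(), epsilon = 0,
                               nsim = 10000, seed = NULL) {
  if (is.character(roster)) roster <- build_population(roster)
  if (is.null(seed)) seed <- new_seed()
  tables <- pair_payoff_tables(roster, config, epsilon, nsim, seed)
  st <- sml_stationary(tables, evo)
  mono <- dplyr::bind_rows(lapply(roster, monomorphic_metrics, config = config,
                                  epsilon = epsilon, nsim = nsim, seed = seed))
  sigma <- unname(st$sigma)
  has_del <- any(vapply(roster, function(s)
    s$mode %in% c("program", "delegate"), logical(1)))
  d_bar <- if (has_del) delegation_rate(sigma, roster) else NA_real_
  strategies <- tibble::tibble(
    label = mono$label, mode = mono$mode, sigma = sigma,
    eta = mono$eta, C = mono$C, epsilon = epsilon
  )
  summary <- tibble::tibble(
    epsilon = epsilon,
    success_rate = success_rate(sigma, mono$eta),
    avg_public_account = avg_public_account(sigma, mono$C),
    delegation_rate = d_bar
  )
  structure(list(summary = summary, strategies = strategies, stationary = st,
                 config = config, evo = evo, nsim = nsim, seed = seed),
            class = "population_metrics")
}

#' @export
print.population_metrics <- function(x, ...) {
  cat("<population_metrics> epsilon =", x$summary$epsilon, "\n")
  print(x$summary)
  invisible(x)
}
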