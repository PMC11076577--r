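#' Collective-risk dilemma configuration
#'
#' Groups of `N` players each hold an endowment `E` and have `r` rounds to
#' contribute, each round an amount from the action set. If the group's
#' public account reaches `threshold` (by default half of the total
#' endowment, `E/2 * N`) the game stops and everyone keeps what remains;
#' otherwise each player loses the remainder with probability `p`. Defaults
#' are the study conditions: `N = 6`, `E = 40`, `r = 10`, actions
#' `{0, 2, 4}`, `p = 0.9`, `threshold = 120`.
#'
#' @param N Group size (players), at least 2.
#' @param E Initial endowment, monetary units.
#' @param r Number of rounds.
#' @param actions Ordered action set; `r * max(actions)` must not exceed `E`.
#' @param p Risk probability in `[0, 1]`.
#' @param threshold Collective target, monetary units.
#' @return An object of class `crd_config`.
#' @export
crd_config <- function(N = 6, E = 40, r = 10, actions = c(0, 2, 4), p = 0.9,
                       threshold = E / 2 * N) {
  actions <- sort(actions)
  stopifnot(N >= 2, E > 0, r >= 1, length(actions) >= 2,
            p >= 0, p <= 1, threshold > 0)
  if (r * max(actions) > E) {
    stop("r * max(actions) must not exceed E: a player can never contribute ",
         "more than the endowment")
  }
  structure(list(N = N, E = E, r = r, actions = actions, p = p,
                 threshold = threshold),
            class = "crd_config")
}

#' @export
print.crd_config <- function(x, ...) {
  cat("<crd_config> N =", x$N, "E =", x$E, "r =", x$r,
      "A = {", paste(x$actions, collapse = ", "), "} p =", x$p,
      "threshold =", x$threshold, "\n")
  invisible(x)
}

# translate a list of strategies into the engine's integer encoding
engine_args <- function(specs, config) {
  L <- length(config$actions)
  profiles <- matrix(0L, nrow = length(specs), ncol = 1 + L)
  modes <- integer(length(specs))
  pool <- canonical_profiles(config$actions)
  pool_mat <- t(vapply(pool, function(pr) {
    c(match(pr$first, config$actions),
      match(unname(pr$response), config$actions)) - 1L
  }, integer(1 + L)))
  pool_index <- integer(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    stopifnot(inherits(s, "crd_strategy"))
    if (!identical(s$profile$actions, config$actions)) {
      stop("strategy '", s$label, "' uses a different action set than the game")
    }
    profiles[i, ] <- c(match(s$profile$first, config$actions),
                       match(unname(s$profile$response), config$actions)) - 1L
    modes[i] <- mode_code(s$mode)
    if (s$mode == "delegate") {
      idx <- which(vapply(pool, profiles_equal, logical(1), b = s$profile))
      if (length(idx) != 1) {
        stop("delegate-mode strategy '", s$label,
             "' must be one of the canonical pool profiles")
      }
      pool_index[i] <- idx - 1L
    }
  }
  list(profiles = profiles, modes = modes, pool = pool_mat,
       pool_index = pool_index)
}

new_seed <- function() sample.int(.Machine$integer.max, 1)

#' Play collective-risk dilemma games
#'
#' Simulates `nsim` games among the given strategies. Before round 1,
#' program- and delegate-mode players realize their effective profile once;
#' execution-mode players pass every intended action through a fresh error
#' draw each round. Contributions within a round are simultaneous and the
#' threshold is checked at round end; afterwards everyone stops contributing.
#' Final payoffs follow the expected-value form of the risk lottery (see
#' [final_payoff()]).
#'
#' @param specs List of `config$N` [strategy_spec()] objects.
#' @param config A [crd_config()].
#' @param epsilon Error probability in `[0, 1]`.
#' @param nsim Number of games to simulate.
#' @param seed Integer seed for the simulation stream; drawn from the R
#'   random number generator when `NULL`.
#' @return A list of class `crd_games`: `payoffs` and `contributions`
#'   (`nsim` x `N` matrices), `public_account`, `success`, `rounds_played`
#'   vectors, plus the configuration. `tidy()` turns it into a per-game
#'   tibble.
#' @examples
#' cfg <- crd_config()
#' g <- play_game(rep(list(strategy_spec("always-4")), 6), cfg)
#' g$rounds_played # 5: 24 per round reaches 120 at round 5
#' @export
play_game <- function(specs, config = crd_config(), epsilon = 0, nsim = 1,
                      seed = NULL) {
  stopifnot(length(specs) == config$N, epsilon >= 0, epsilon <= 1, nsim >= 1)
  if (is.null(seed)) seed <- new_seed()
  ea <- engine_args(specs, config)
  out <- crd_sim_games(ea$profiles, ea$modes, config$actions, config$E,
                       config$r, config$p, config$threshold, epsilon,
                       ea$pool, ea$pool_index, as.integer(nsim),
                       as.numeric(seed), FALSE)
  structure(
    list(payoffs = out$payoffs, contributions = out$contributions,
         public_account = out$public_account, success = out$success,
         rounds_played = out$rounds, config = config, epsilon = epsilon,
         seed = seed,
         labels = vapply(specs, function(s) s$label, character(1))),
    class = "crd_games"
  )
}

#' @export
print.crd_games <- function(x, ...) {
  cat("<crd_games>", nrow(x$payoffs), "game(s),", x$config$N, "players",
      "| epsilon =", x$epsilon, "\n")
  cat("  mean public account:", mean(x$public_account),
      "| success rate:", mean(x$success), "\n")
  invisible(x)
}

#' Final payoff of a player under the expected-value risk lottery
#'
#' On success a player keeps the remaining endowment; on failure the
#' remainder is kept only with probability `1 - p`, and the expected value
#' `remaining * (1 - p)` is used directly rather than sampling the disaster.
#'
#' @param remaining Endowment minus the player's total contribution
#'   (non-negative).
#' @param success Logical: did the group reach the threshold?
#' @param p Risk probability.
#' @return Numeric payoff(s), in `[0, E]`.
#' @examples
#' final_payoff(20, TRUE, 0.9)  # 20
#' final_payoff(20, FALSE, 0.9) # 2
#' @export
final_payoff <- function(remaining, success, p) {
  stopifnot(all(remaining >= 0), p >= 0, p <= 1)
  remaining * ifelse(success, 1, 1 - p)
}
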