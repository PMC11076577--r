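#' Tidy a stationary distribution
#'
#' @param x A `stationary_result` from [sml_stationary()].
#' @param ... Unused.
#' @return Tibble with one row per strategy: `label`, `mode`, `sigma`.
#' @export
tidy.stationary_result <- function(x, ...) {
  tibble::tibble(
    label = vapply(x$roster, function(s) s$label, character(1)),
    mode = vapply(x$roster, function(s) s$mode, character(1)),
    sigma = unname(x$sigma)
  )
}

#' One-line summary of a stationary distribution
#'
#' @inheritParams tidy.stationary_result
#' @return One-row tibble: roster size, `Z`, `beta`, `epsilon`, and the mass
#'   on delegation strategies.
#' @export
glance.stationary_result <- function(x, ...) {
  del <- vapply(x$roster, function(s) s$mode %in% c("program", "delegate"),
                logical(1))
  tibble::tibble(S = length(x$sigma), Z = x$Z, beta = x$beta,
                 epsilon = x$epsilon %||% NA_real_,
                 delegation_mass = if (any(del)) sum(x$sigma[del]) else NA_real_)
}

#' Tidy an error-probability sweep
#'
#' @param x A `crd_sweep` from [sweep_epsilon()].
#' @param level `"population"` for the per-epsilon averages, `"strategy"`
#'   for the per-strategy stationary distribution and monomorphic metrics.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crd_sweep <- function(x, level = c("population", "strategy"), ...) {
  level <- match.arg(level)
  if (level == "population") x$summary else x$strategies
}

#' One-line summary of a sweep
#'
#' @inheritParams tidy.crd_sweep
#' @return One-row tibble with the population kind, grid span and size,
#'   roster size, `nsim` and the evolutionary parameters.
#' @export
glance.crd_sweep <- function(x, ...) {
  tibble::tibble(kind = x$kind %||% "custom", n_epsilon = length(x$grid),
                 eps_min = min(x$grid), eps_max = max(x$grid),
                 S = length(x$roster), nsim = x$nsim,
                 Z = x$evo$Z, beta = x$evo$beta)
}

#' Tidy simulated games
#'
#' @param x A `crd_games` from [play_game()].
#' @param ... Unused.
#' @return Tibble with one row per game and player: `game`, `player`,
#'   `label`, `contribution`, `payoff`, `public_account`, `success`,
#'   `rounds_played`.
#' @export
tidy.crd_games <- function(x, ...) {
  n <- nrow(x$payoffs)
  N <- ncol(x$payoffs)
  tibble::tibble(
    game = rep(seq_len(n), each = N),
    player = rep(seq_len(N), n),
    label = rep(x$labels, n),
    contribution = as.vector(t(x$contributions)),
    payoff = as.vector(t(x$payoffs)),
    public_account = rep(x$public_account, each = N),
    success = rep(x$success, each = N),
    rounds_played = rep(x$rounds_played, each = N)
  )
}
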