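# Exhaustive-enumeration oracle for pairwise payoff tables.
# Sums deterministic playouts over every error realization, weighted by its
# probability: one-shot profile realizations for program/delegate players and
# per-round action branches for execution players. Exact, but exponential in
# the number of execution player-rounds, hence restricted to tiny games.

profile_outcomes <- function(spec, actions, epsilon, pool) {
  L <- length(actions)
  switch(spec$mode,
    none = ,
    execution = list(list(p = spec$profile, w = 1)),
    delegate = {
      idx <- which(vapply(pool, profiles_equal, logical(1), b = spec$profile))
      if (length(idx) != 1) stop("delegate profile must be in the pool")
      out <- list()
      for (k in seq_along(pool)) {
        w <- if (k == idx) 1 - epsilon else epsilon / (length(pool) - 1)
        if (w > 0) out[[length(out) + 1]] <- list(p = pool[[k]], w = w)
      }
      out
    },
    program = {
      params <- c(spec$profile$first, unname(spec$profile$response))
      per <- lapply(params, function(v) {
        wts <- rep(epsilon / (L - 1), L)
        wts[match(v, actions)] <- 1 - epsilon
        keep <- wts > 0
        list(vals = actions[keep], wts = wts[keep])
      })
      grid <- expand.grid(lapply(per, function(x) seq_along(x$vals)))
      lapply(seq_len(nrow(grid)), function(g) {
        idxs <- as.integer(grid[g, ])
        vals <- mapply(function(p, i) p$vals[i], per, idxs)
        w <- prod(mapply(function(p, i) p$wts[i], per, idxs))
        list(p = behavior_profile(vals[1], vals[-1], actions), w = w)
      })
    },
    stop("unknown mode"))
}

# expected per-player payoffs of one group, summing over all realizations
oracle_group_payoffs <- function(specs, config, epsilon, max_leaves) {
  N <- config$N
  actions <- config$actions
  L <- length(actions)
  pool <- canonical_profiles(actions)
  outcomes <- lapply(specs, profile_outcomes, actions = actions,
                     epsilon = epsilon, pool = pool)
  n_exec <- sum(vapply(specs, function(s) s$mode == "execution", logical(1)) &
                  epsilon > 0)
  bound <- prod(vapply(outcomes, length, integer(1))) *
    (L^n_exec)^config$r
  if (bound > max_leaves) {
    stop("enumeration state space (", format(bound),
         " leaves) exceeds max_leaves = ", max_leaves)
  }
  is_exec <- vapply(specs, function(s) s$mode == "execution", logical(1))
  acc <- numeric(N)

  playout <- function(effs, k, prev, contrib, pub, w) {
    if (pub >= config$threshold || k >= config$r) {
      success <- pub >= config$threshold
      acc <<- acc + w * final_payoff(config$E - contrib, success, config$p)
      return(invisible())
    }
    # intended action of each player this round
    intents <- vapply(seq_len(N), function(i) {
      if (k == 0) effs[[i]]$first
      else intended_action(effs[[i]], k, (sum(prev) - prev[i]) / (N - 1))
    }, numeric(1))
    # per-player emitted-action options with probabilities
    opts <- lapply(seq_len(N), function(i) {
      if (is_exec[i] && epsilon > 0) {
        wts <- rep(epsilon / (L - 1), L)
        wts[match(intents[i], actions)] <- 1 - epsilon
        list(vals = actions, wts = wts)
      } else {
        list(vals = intents[i], wts = 1)
      }
    })
    recurse <- function(i, acts, wr) {
      if (i > N) {
        playout(effs, k + 1, acts, contrib + acts, pub + sum(acts), w * wr)
        return(invisible())
      }
      o <- opts[[i]]
      for (t in seq_along(o$vals)) {
        if (o$wts[t] > 0) {
          acts[i] <- o$vals[t]
          recurse(i + 1, acts, wr * o$wts[t])
        }
      }
    }
    recurse(1, numeric(N), 1)
  }

  combo <- function(i, effs, w) {
    if (i > N) {
      playout(effs, 0, numeric(N), numeric(N), 0, w)
      return(invisible())
    }
    for (o in outcomes[[i]]) combo(i + 1, c(effs, list(o$p)), w * o$w)
  }
  combo(1, list(), 1)
  acc
}

#' Exact pairwise payoff table by exhaustive enumeration
#'
#' Brute-force verification oracle for [estimate_pair_payoffs()]: expected
#' payoffs are computed exactly by summing deterministic playouts over every
#' error realization, weighted by its probability. Feasible only for tiny
#' games (small `N`, `r`, or delegate/program modes); the call refuses when
#' the enumeration bound exceeds `max_leaves`.
#'
#' @inheritParams estimate_pair_payoffs
#' @param max_leaves Cap on the enumerated state-space size.
#' @return A `pair_payoff_table` tibble, as [estimate_pair_payoffs()].
#' @export
enumerate_pair_payoffs_oracle <- function(a, b, config, epsilon = 0,
                                          max_leaves = 2e5) {
  stopifnot(inherits(a, "crd_strategy"), inherits(b, "crd_strategy"),
            epsilon >= 0, epsilon <= 1)
  N <- config$N
  pi_a <- rep(NA_real_, N)
  pi_b <- rep(NA_real_, N)
  for (na in 0:N) {
    specs <- c(rep(list(a), na), rep(list(b), N - na))
    acc <- oracle_group_payoffs(specs, config, epsilon, max_leaves)
    if (na > 0) pi_a[na] <- mean(acc[seq_len(na)])
    if (na < N) pi_b[na + 1] <- mean(acc[(na + 1):N])
  }
  new_pair_table(0:(N - 1), pi_a, pi_b, a, b, epsilon, NA_integer_, NA_real_)
}
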