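#' Evolutionary dynamics configuration
#'
#' Finite well-mixed population of `Z` imitating individuals; imitation
#' follows the Fermi rule with selection strength `beta`. Defaults are the
#' study conditions `Z = 100`, `beta = 0.05`.
#'
#' @param Z Population size (must be at least the group size of the game).
#' @param beta Selection strength (non-negative, dimensionless).
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(Z = 100, beta = 0.05) {
  stopifnot(Z >= 2, beta >= 0)
  structure(list(Z = Z, beta = beta), class = "evolution_config")
}

#' Fermi imitation probability
#'
#' Probability that an individual imitates a role model whose fitness exceeds
#' its own by `payoff_gap`: `1 / (1 + exp(-beta * payoff_gap))`. Overflow-safe
#' for arbitrarily large gaps.
#'
#' @param beta Selection strength.
#' @param payoff_gap Role model's fitness minus the focal individual's.
#' @return Probability in `[0, 1]`.
#' @export
fermi_prob <- function(beta, payoff_gap) {
  stopifnot(beta >= 0)
  plogis(beta * payoff_gap)
}

#' Population-level fitness of two competing strategies
#'
#' With `m` A-individuals among `Z`, a focal player's `N - 1` co-players are
#' drawn without replacement from the other `Z - 1` individuals, so the
#' number of A-co-players is hypergeometric. Fitness is the expectation of
#' the pairwise payoff table under those weights.
#'
#' @param m Count of A-individuals, `1 <= m <= Z - 1`.
#' @param table A `pair_payoff_table` from [estimate_pair_payoffs()].
#' @param Z Population size.
#' @param N Game group size (defaults to the table's length).
#' @return Named numeric vector `c(f_A, f_B)`.
#' @export
group_fitness <- function(m, table, Z, N = nrow(table)) {
  stopifnot(m >= 1, m <= Z - 1, Z >= N)
  j <- 0:(N - 1)
  c(f_A = sum(dhyper(j, m - 1, Z - m, N - 1) * table$pi_a),
    f_B = sum(dhyper(j, m, Z - m - 1, N - 1) * table$pi_b))
}

# fitness gaps f_B(m_A) - f_A(m_A) for every interior state m_A = 1..Z-1
fitness_gaps <- function(table, Z) {
  N <- nrow(table)
  f <- vapply(1:(Z - 1), group_fitness, numeric(2), table = table, Z = Z,
              N = N)
  list(f_a = f[1, ], f_b = f[2, ])
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Pairwise fixation probabilities under the Fermi rule
#'
#' Closed form for the probability that a single mutant takes over a resident
#' population under pairwise comparison with imitation probability
#' [fermi_prob()]: `rho = 1 / (1 + sum_k prod_m exp(-beta * gap(m)))`, where
#' `gap(m)` is the mutant-minus-resident fitness difference at `m` mutants.
#' The products are accumulated in log space.
#'
#' @inheritParams group_fitness
#' @param beta Selection strength.
#' @return Named numeric vector: `b_invades_a` (one B-mutant fixing in an
#'   A-resident population) and `a_invades_b` (the reverse).
#' @export
fixation_probability <- function(table, Z, beta) {
  stopifnot(Z >= 2, beta >= 0)
  g <- fitness_gaps(table, Z)
  rho <- function(log_gamma) {
    # 1 / (1 + sum_k exp(cumsum_k)) = exp(-logsumexp(c(0, cumsums)))
    exp(-logsumexp(c(0, cumsum(log_gamma))))
  }
  # B invading A: i mutants B means m_A = Z - i, i = 1..Z-1
  lg_b <- -beta * (g$f_b[Z - (1:(Z - 1))] - g$f_a[Z - (1:(Z - 1))])
  # A invading B: i mutants A means m_A = i
  lg_a <- -beta * (g$f_a[1:(Z - 1)] - g$f_b[1:(Z - 1)])
  c(b_invades_a = rho(lg_b), a_invades_b = rho(lg_a))
}

#' Fixation probability by explicit birth-death chain solution
#'
#' Independent cross-check of [fixation_probability()]: builds the full
#' `(Z + 1)`-state birth-death Markov chain of the pairwise-comparison
#' process (mutant count 0..Z, Fermi imitation probabilities) and solves the
#' absorption probabilities linearly. Intended for small `Z`.
#'
#' @inheritParams fixation_probability
#' @return Probability that a single B-mutant fixes in an A-resident
#'   population.
#' @export
fixation_bd_oracle <- function(table, Z, beta) {
  g <- fitness_gaps(table, Z)
  # state i = number of B mutants; m_A = Z - i
  i <- 1:(Z - 1)
  gap <- g$f_b[Z - i] - g$f_a[Z - i]
  t_up <- (Z - i) / Z * i / (Z - 1) * fermi_prob(beta, gap)
  t_dn <- i / Z * (Z - i) / (Z - 1) * fermi_prob(beta, -gap)
  # solve h(i) = P(absorb at Z | start i); h(0) = 0, h(Z) = 1
  A <- matrix(0, Z - 1, Z - 1)
  b <- numeric(Z - 1)
  for (s in i) {
    A[s, s] <- -(t_up[s] + t_dn[s])
    if (s > 1) A[s, s - 1] <- t_dn[s]
    if (s < Z - 1) A[s, s + 1] <- t_up[s]
    if (s == Z - 1) b[s] <- -t_up[s]
  }
  solve(A, b)[1]
}

#' Matrix of pairwise fixation probabilities for a roster
#'
#' @param tables A `pair_table_set` from [pair_payoff_tables()].
#' @param Z Population size.
#' @param beta Selection strength.
#' @return `S x S` matrix; entry `[i, j]` is the probability that a single
#'   `j`-mutant fixes in an `i`-resident population. Diagonal is `NA`.
#' @export
fixation_matrix <- function(tables, Z, beta) {
  roster <- attr(tables, "roster")
  S <- length(roster)
  rho <- matrix(NA_real_, S, S)
  labels <- vapply(roster, function(s) s$label, character(1))
  dimnames(rho) <- list(resident = labels, mutant = labels)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i != j) {
        rho[i, j] <- fixation_probability(tables[[i, j]], Z, beta)["b_invades_a"]
      }
    }
  }
  rho
}

#' Small-mutation-limit stationary distribution
#'
#' In the small-mutation limit the population is almost always monomorphic
#' and evolution reduces to a Markov chain over the `S` roster strategies:
#' the transition from state `i` to `j != i` is `rho[i, j] / (S - 1)`
#' (mutants appear uniformly among the other strategies and imitation copies
#' the originally intended strategy, error mode included). `sigma` is the
#' normalized left eigenvector of the transition matrix at eigenvalue 1;
#' small negative numerical residues are clamped to zero before
#' renormalizing.
#'
#' @param tables A `pair_table_set` from [pair_payoff_tables()].
#' @param evo An [evolution_config()].
#' @return An object of class `stationary_result`: `sigma` (named),
#'   `transition_matrix`, `fixation`, plus `Z`, `beta` and the roster.
#' @export
sml_stationary <- function(tables, evo = evolution_config()) {
  roster <- attr(tables, "roster")
  S <- length(roster)
  rho <- fixation_matrix(tables, evo$Z, evo$beta)
  if (any(rho[!is.na(rho)] <= 0)) {
    stop("all pairwise fixation probabilities must be positive")
  }
  M <- rho / (S - 1)
  diag(M) <- 0
  diag(M) <- 1 - rowSums(M)
  A <- rbind(t(M) - diag(S), rep(1, S))
  b <- c(rep(0, S), 1)
  sigma <- qr.solve(A, b)
  sigma[sigma < 0] <- 0
  sigma <- sigma / sum(sigma)
  names(sigma) <- rownames(rho)
  structure(list(sigma = sigma, transition_matrix = M, fixation = rho,
                 Z = evo$Z, beta = evo$beta, roster = roster,
                 epsilon = attr(tables, "epsilon")),
            class = "stationary_result")
}

#' @export
print.stationary_result <- function(x, ...) {
  cat("<stationary_result> S =", length(x$sigma), "Z =", x$Z,
      "beta =", x$beta, "\n")
  print(round(x$sigma, 4))
  invisible(x)
}
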