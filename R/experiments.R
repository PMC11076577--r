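.population_kinds <- c("execution-only", "program-only", "delegate-only",
                       "hybrid-program", "hybrid-delegate")

#' Build a strategy roster for a population experiment
#'
#' Single-mode populations carry the five canonical behavioral profiles under
#' one error mode (`S = 5`); hybrid populations add a delegation-mode copy of
#' each profile next to the execution-mode one (`S = 10`), so that the choice
#' to delegate itself evolves. Rosters are deterministic and in canonical
#' order: always-0, always-2, always-4, reciprocal, compensatory (hybrids
#' append the delegation-mode copies in the same order).
#'
#' @param kind One of `"execution-only"`, `"program-only"`,
#'   `"delegate-only"`, `"hybrid-program"`, `"hybrid-delegate"`.
#' @param actions Ordered action set of the underlying game.
#' @return A list of [strategy_spec()] objects with attribute `kind`.
#' @examples
#' length(build_population("hybrid-program")) # 10
#' @export
build_population <- function(kind, actions = c(0, 2, 4)) {
  if (!kind %in% .population_kinds) {
    stop("unknown population kind '", kind, "'; valid kinds: ",
         paste(.population_kinds, collapse = ", "))
  }
  profs <- canonical_profiles(actions)
  make <- function(mode, tag = mode) {
    lapply(names(profs), function(nm) {
      strategy_spec(profs[[nm]], mode, label = paste0(nm, " (", tag, ")"))
    })
  }
  roster <- switch(kind,
    "execution-only" = make("execution"),
    "program-only" = make("program"),
    "delegate-only" = make("delegate"),
    "hybrid-program" = c(make("execution"), make("program")),
    "hybrid-delegate" = c(make("execution"), make("delegate"))
  )
  structure(roster, kind = kind, class = c("crd_roster", "list"))
}

#' Sweep the error probability for one population
#'
#' For every grid point, computes all pairwise payoff tables, the
#' small-mutation-limit stationary distribution, per-strategy monomorphic
#' metrics and the population averages. Fully reproducible given `seed`
#' (each `epsilon` runs on a deterministic child stream).
#'
#' @param population A roster from [build_population()] or a kind string.
#' @param grid Strictly increasing error probabilities in `[0, 1]`.
#' @param config A [crd_config()].
#' @param evo An [evolution_config()].
#' @param nsim Simulated games per group composition.
#' @param seed Integer base seed.
#' @return An object of class `crd_sweep`: `summary` (one row per grid
#'   point: `epsilon`, `success_rate`, `avg_public_account`,
#'   `delegation_rate`) and `strategies` (per-strategy rows: `sigma`, `eta`,
#'   `C`), plus metadata.
#' @export
sweep_epsilon <- function(population, grid = seq(0, 0.5, by = 0.02),
                          config = crd_config(), evo = evolution_config(),
                          nsim = 10000, seed = NULL) {
  stopifnot(all(grid >= 0), all(grid <= 1), !is.unsorted(grid, strictly = TRUE))
  if (is.character(population)) population <- build_population(population,
                                                               config$actions)
  if (is.null(seed)) seed <- new_seed()
  rows <- lapply(grid, function(eps) {
    child <- key_seed(seed, sprintf("eps=%.10g", eps))
    population_metrics(population, config, evo, eps, nsim, child)
  })
  structure(
    list(summary = dplyr::bind_rows(lapply(rows, `[[`, "summary")),
         strategies = dplyr::bind_rows(lapply(rows, `[[`, "strategies")),
         kind = attr(population, "kind"), roster = population, grid = grid,
         config = config, evo = evo, nsim = nsim, seed = seed),
    class = "crd_sweep"
  )
}

#' @export
print.crd_sweep <- function(x, ...) {
  cat("<crd_sweep>", x$kind %||% "custom roster", "|",
      length(x$grid), "epsilon points, nsim =", x$nsim, "\n")
  print(x$summary, n = 6)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First crossing of two curves on a common grid
#'
#' Finds the smallest abscissa where `f - g` changes sign, by linear
#' interpolation between the bracketing grid points. Differences smaller
#' than `tol` in absolute value are treated as ties (the curves touching)
#' and never seed a crossing on their own; identical curves are reported
#' distinctly from curves that simply never cross.
#'
#' @param x Strictly increasing grid.
#' @param f,g Curve values on `x` (same length).
#' @param tol Absolute tolerance below which `f - g` counts as zero.
#' @return A one-row tibble: `status` (`"crossing"`, `"none"` or
#'   `"identical"`), the interpolated `x_cross`, and the bracketing grid
#'   values `x_lo`, `x_hi` (`NA` unless a crossing is found).
#' @examples
#' find_crossing(seq(0, 1, 0.25), 1 - seq(0, 1, 0.25), seq(0, 1, 0.25))
#' @export
find_crossing <- function(x, f, g, tol = 1e-9) {
  stopifnot(length(x) == length(f), length(f) == length(g),
            !is.unsorted(x, strictly = TRUE))
  d <- f - g
  d[abs(d) < tol] <- 0
  none <- tibble::tibble(status = "none", x_cross = NA_real_,
                         x_lo = NA_real_, x_hi = NA_real_)
  nz <- which(d != 0)
  if (length(nz) == 0) {
    none$status <- "identical"
    return(none)
  }
  s <- sign(d[nz])
  flip <- which(s[-1] != s[-length(s)])
  if (length(flip) == 0) {
    return(none)
  }
  i <- nz[flip[1]]
  j <- nz[flip[1] + 1]
  if (j > i + 1) {
    # the curves touch on a zero run between the brackets; first touch point
    return(tibble::tibble(status = "crossing", x_cross = x[i + 1],
                          x_lo = x[i], x_hi = x[j]))
  }
  x_cross <- x[i] + (x[j] - x[i]) * d[i] / (d[i] - d[j])
  tibble::tibble(status = "crossing", x_cross = x_cross,
                 x_lo = x[i], x_hi = x[j])
}

#' Crossings between two sweeps on a common metric
#'
#' Convenience wrapper around [find_crossing()] for two [sweep_epsilon()]
#' results computed on the same grid.
#'
#' @param sweep_f,sweep_g `crd_sweep` objects with identical grids.
#' @param metric Column of the sweep summary to compare.
#' @inheritParams find_crossing
#' @return As [find_crossing()].
#' @export
sweep_crossing <- function(sweep_f, sweep_g,
                           metric = c("success_rate", "avg_public_account",
                                      "delegation_rate"),
                           tol = 1e-9) {
  metric <- match.arg(metric)
  stopifnot(identical(sweep_f$grid, sweep_g$grid))
  find_crossing(sweep_f$grid, sweep_f$summary[[metric]],
                sweep_g$summary[[metric]], tol = tol)
}

#' Smallest error probability at which one strategy overtakes others
#'
#' Scans a sweep's per-strategy stationary distribution for the first
#' (interpolated) `epsilon` where `label`'s mass exceeds the maximum over
#' `over` -- used to locate the rise of the selfish strategy over the
#' reciprocal / always-2 / compensatory drift triad.
#'
#' @param sweep A `crd_sweep`.
#' @param label Strategy label whose dominance is sought.
#' @param over Character vector of competitor labels.
#' @inheritParams find_crossing
#' @return As [find_crossing()].
#' @export
dominance_crossing <- function(sweep, label, over, tol = 1e-9) {
  sig <- tidyr::pivot_wider(sweep$strategies[, c("epsilon", "label", "sigma")],
                            names_from = "label", values_from = "sigma")
  stopifnot(label %in% names(sig), all(over %in% names(sig)))
  top <- do.call(pmax, unname(as.list(sig[, over, drop = FALSE])))
  find_crossing(sig$epsilon, sig[[label]], top, tol = tol)
}
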