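#' Map a co-players' average onto the nearest anchor action
#'
#' Conditional (memory-1) profiles are only defined at the anchor actions of
#' the action set `A`. When the co-players' mean contribution falls between
#' anchors, it is assigned to the nearest one, with boundaries at the
#' midpoints between consecutive anchors; an exact midpoint rounds to the
#' higher anchor. The result is monotone non-decreasing in `avg`.
#'
#' @param avg Numeric vector of mean co-player contributions; each value must
#'   lie within `[min(actions), max(actions)]`.
#' @param actions Ordered action set (default `c(0, 2, 4)`).
#' @return Numeric vector of anchor actions, same length as `avg`.
#' @examples
#' bin_others_average(c(2, 2.67, 1, 3.5))
#' @export
bin_others_average <- function(avg, actions = c(0, 2, 4)) {
  stopifnot(is.numeric(avg), is.numeric(actions), length(actions) >= 2)
  actions <- sort(actions)
  if (any(avg < actions[1] | avg > actions[length(actions)])) {
    stop("`avg` must lie within [min(actions), max(actions)]")
  }
  mid <- (actions[-1] + actions[-length(actions)]) / 2
  idx <- vapply(avg, function(a) 1L + sum(a >= mid), integer(1))
  actions[idx]
}

#' Construct a memory-1 behavioral profile
#'
#' A profile is a small program with `1 + |A|` settings: the first-round
#' action plus one response per anchor action (what to contribute if the
#' co-players averaged that anchor in the previous round).
#'
#' @param first First-round action; must be in `actions`.
#' @param response Numeric vector, one response per anchor of `actions`
#'   (ascending anchor order); all values must be in `actions`.
#' @param actions Ordered action set.
#' @return An object of class `crd_profile`.
#' @examples
#' reciprocal <- behavior_profile(2, c(0, 2, 4))
#' compensatory <- behavior_profile(2, c(4, 2, 0))
#' @export
behavior_profile <- function(first, response, actions = c(0, 2, 4)) {
  actions <- sort(actions)
  stopifnot(length(first) == 1, length(response) == length(actions))
  if (!first %in% actions || !all(response %in% actions)) {
    stop("profile entries must be actions from the action set")
  }
  structure(
    list(first = first, response = setNames(as.numeric(response),
                                            as.character(actions)),
         actions = actions),
    class = "crd_profile"
  )
}

#' @export
print.crd_profile <- function(x, ...) {
  cat("<crd_profile> first:", x$first, "| response:",
      paste(names(x$response), "->", x$response, collapse = ", "), "\n")
  invisible(x)
}

#' The five canonical behavioral profiles
#'
#' Returns the pool of pre-set agents studied throughout: the three
#' unconditional profiles (always contribute the same amount), the reciprocal
#' profile (match the co-players' previous average) and the compensatory
#' profile (contribute what the co-players did not). Both conditional
#' profiles open with the middle action.
#'
#' @param actions Ordered action set; with the default `c(0, 2, 4)` the names
#'   are `always-0`, `always-2`, `always-4`, `reciprocal`, `compensatory`.
#' @return Named list of [behavior_profile()] objects in canonical order.
#' @export
canonical_profiles <- function(actions = c(0, 2, 4)) {
  actions <- sort(actions)
  L <- length(actions)
  mid <- actions[ceiling((L + 1) / 2)]
  fixed <- lapply(actions, function(v) {
    behavior_profile(v, rep(v, L), actions)
  })
  names(fixed) <- paste0("always-", vapply(actions, format, character(1)))
  c(fixed,
    list(reciprocal = behavior_profile(mid, actions, actions),
         compensatory = behavior_profile(mid, rev(actions), actions)))
}

#' Pair a behavioral profile with an error mode
#'
#' A strategy is the heritable unit of the evolutionary process: the intended
#' profile plus the mode in which mistakes occur. `execution` errors fire at
#' every round (direct play); `program` and `delegate` errors fire once per
#' game, before the first round (delegation); `none` disables errors. Two
#' strategies are equal iff profile and mode are equal; labels are cosmetic.
#'
#' @param profile A [behavior_profile()], or the name of a canonical profile.
#' @param error_mode One of `"none"`, `"execution"`, `"program"`, `"delegate"`.
#' @param label Optional human-readable name.
#' @return An object of class `crd_strategy`.
#' @examples
#' strategy_spec("always-2", "delegate")
#' @export
strategy_spec <- function(profile, error_mode = "none", label = NULL) {
  error_mode <- match.arg(error_mode, names(.mode_levels))
  if (is.character(profile)) {
    prof_name <- profile
    pool <- canonical_profiles()
    if (!prof_name %in% names(pool)) {
      stop("unknown canonical profile '", prof_name, "'; valid names: ",
           paste(names(pool), collapse = ", "))
    }
    profile <- pool[[prof_name]]
    if (is.null(label)) label <- prof_name
  }
  stopifnot(inherits(profile, "crd_profile"))
  if (is.null(label)) label <- "strategy"
  structure(list(profile = profile, mode = error_mode, label = label),
            class = "crd_strategy")
}

#' @export
print.crd_strategy <- function(x, ...) {
  cat("<crd_strategy>", x$label, "[", x$mode, "] first:", x$profile$first,
      "response:", paste(x$profile$response, collapse = "/"), "\n")
  invisible(x)
}

# canonical serialization; equality and seed derivation ignore labels
spec_key <- function(spec) {
  paste(spec$mode, spec$profile$first,
        paste(spec$profile$response, collapse = ","), sep = "|")
}

#' Test two strategies for equality
#'
#' Labels are cosmetic: strategies are equal iff their intended profiles and
#' error modes coincide.
#'
#' @param a,b [strategy_spec()] objects.
#' @return Logical scalar.
#' @export
specs_equal <- function(a, b) {
  identical(spec_key(a), spec_key(b)) &&
    identical(a$profile$actions, b$profile$actions)
}

profiles_equal <- function(a, b) {
  identical(a$first, b$first) &&
    identical(unname(a$response), unname(b$response)) &&
    identical(a$actions, b$actions)
}

#' Intended action of a profile at a given round
#'
#' @param profile A [behavior_profile()].
#' @param round_index Non-negative integer; 0 is the first round.
#' @param prev_others_avg Mean contribution of the co-players in the previous
#'   round; must be absent (`NULL`) iff `round_index == 0`.
#' @return The action the profile prescribes.
#' @export
intended_action <- function(profile, round_index, prev_others_avg = NULL) {
  stopifnot(inherits(profile, "crd_profile"), round_index >= 0)
  if (round_index == 0) {
    return(profile$first)
  }
  if (is.null(prev_others_avg)) {
    stop("`prev_others_avg` is required after the first round")
  }
  anchor <- bin_others_average(prev_others_avg, profile$actions)
  unname(profile$response[as.character(anchor)])
}

# uniform draw over the action set minus the excluded value
sample_other <- function(values, exclude_index, n) {
  others <- values[-exclude_index]
  others[sample.int(length(others), n, replace = TRUE)]
}

#' Realize execution errors on an intended action
#'
#' With probability `1 - epsilon` the intended action is emitted; with
#' probability `epsilon` a uniformly chosen *other* action is emitted, so
#' `epsilon` is the exact per-round deviation probability. Draws use the R
#' random number generator.
#'
#' @param intended Intended action (in `actions`).
#' @param epsilon Error probability in `[0, 1]`.
#' @param actions Ordered action set.
#' @param n Number of independent realizations to draw.
#' @return Numeric vector of `n` emitted actions.
#' @export
realize_execution <- function(intended, epsilon, actions = c(0, 2, 4), n = 1) {
  stopifnot(epsilon >= 0, epsilon <= 1, intended %in% actions)
  out <- rep(intended, n)
  flip <- runif(n) < epsilon
  k <- sum(flip)
  if (k > 0) out[flip] <- sample_other(actions, match(intended, actions), k)
  out
}

#' Realize program errors on a behavioral profile
#'
#' Each of the `1 + |A|` profile parameters is independently, with probability
#' `epsilon`, replaced by a uniform draw over the other admissible actions.
#' The perturbation is one-shot: it happens before the game and the realized
#' profile is then executed perfectly.
#'
#' @inheritParams realize_execution
#' @param profile Intended [behavior_profile()].
#' @return A realized [behavior_profile()].
#' @export
realize_program <- function(profile, epsilon, actions = profile$actions) {
  stopifnot(inherits(profile, "crd_profile"), epsilon >= 0, epsilon <= 1)
  params <- c(profile$first, unname(profile$response))
  flip <- runif(length(params)) < epsilon
  for (i in which(flip)) {
    params[i] <- sample_other(actions, match(params[i], actions), 1)
  }
  behavior_profile(params[1], params[-1], actions)
}

#' Realize delegate errors on a choice from a pool of pre-set agents
#'
#' With probability `1 - epsilon` the intended agent is selected; with
#' probability `epsilon` one of the other agents in the pool is selected
#' uniformly. One-shot, before the game; the selected profile is then
#' executed perfectly.
#'
#' @inheritParams realize_program
#' @param pool List of [behavior_profile()] objects; must contain `profile`.
#' @return A [behavior_profile()] drawn from the pool.
#' @export
realize_delegate <- function(profile, pool = canonical_profiles(),
                             epsilon = 0) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  idx <- which(vapply(pool, profiles_equal, logical(1), b = profile))
  if (length(idx) != 1) {
    stop("`profile` must appear exactly once in `pool`")
  }
  if (runif(1) < epsilon) {
    idx <- sample_other(seq_along(pool), idx, 1)
  }
  pool[[idx]]
}
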