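#' Plot an error-probability sweep
#'
#' @param object A `crd_sweep` from [sweep_epsilon()].
#' @param metric `"success_rate"`, `"avg_public_account"` or
#'   `"delegation_rate"` for the population curve, `"sigma"`, `"eta"` or
#'   `"C"` for per-strategy curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crd_sweep <- function(object,
                               metric = c("success_rate",
                                          "avg_public_account",
                                          "delegation_rate",
                                          "sigma", "eta", "C"),
                               ...) {
  metric <- match.arg(metric)
  if (metric %in% c("sigma", "eta", "C")) {
    ggplot2::ggplot(object$strategies,
                    ggplot2::aes(x = .data$epsilon, y = .data[[metric]],
                                 colour = .data$label,
                                 linetype = .data$mode)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "error probability", y = metric,
                    title = object$kind %||% "custom roster") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$summary,
                    ggplot2::aes(x = .data$epsilon, y = .data[[metric]])) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "error probability", y = metric,
                    title = object$kind %||% "custom roster") +
      ggplot2::theme_minimal()
  }
}

#' Compare population curves across sweeps
#'
#' Overlays one population-level metric for several sweeps (for example the
#' execution-, program- and delegate-errors populations) on a shared
#' error-probability axis.
#'
#' @param sweeps Named list of `crd_sweep` objects on a common grid.
#' @param metric Summary column to draw.
#' @return A ggplot object.
#' @export
plot_sweep_comparison <- function(sweeps,
                                  metric = c("success_rate",
                                             "avg_public_account",
                                             "delegation_rate")) {
  metric <- match.arg(metric)
  if (is.null(names(sweeps))) {
    names(sweeps) <- vapply(sweeps, function(s) s$kind %||% "custom",
                            character(1))
  }
  dat <- dplyr::bind_rows(lapply(sweeps, tidy, level = "population"),
                          .id = "population")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epsilon, y = .data[[metric]],
                                    colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "error probability", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a stationary distribution
#'
#' @param object A `stationary_result` from [sml_stationary()].
#' @param ... Unused.
#' @return A ggplot bar chart of the stationary mass per strategy.
#' @export
autoplot.stationary_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$sigma,
                                    fill = .data$mode)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "stationary mass") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
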