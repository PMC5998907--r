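# ggplot2 views of trajectories, weights, and comparison sweeps.

#' @export
autoplot.selection_trajectory <- function(object, ...) {
  s_bar <- attr(object, "s_bar")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation, y = .data$s)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = s_bar, linetype = "dashed") +
    ggplot2::labs(x = "generation k", y = expression(s[k]),
                  title = "Per-generation selective advantage",
                  subtitle = sprintf("reference advantage %.4g", s_bar))
}

#' @export
autoplot.comparison_sweep <- function(object, ...) {
  swept <- attr(object, "swept")
  xvar <- if (length(swept) > 0L) swept[[1]] else "p_exact"
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c(xvar, "p_exact", "p_approx")],
    cols = c("p_exact", "p_approx"),
    names_to = "method", values_to = "p"
  )
  gg <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data[[xvar]], y = .data$p,
                                     colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = "fixation probability",
                  title = "Approximation vs exact iteration")
  if ("mc_estimate" %in% names(object)) {
    gg <- gg + ggplot2::geom_pointrange(
      data = as_tibble(object),
      ggplot2::aes(x = .data[[xvar]], y = .data$mc_estimate,
                   ymin = .data$mc_estimate - .data$mc_ci99,
                   ymax = .data$mc_estimate + .data$mc_ci99),
      inherit.aes = FALSE, colour = "grey40"
    )
  }
  gg
}

#' Plot the geometric weights of the effective advantage
#'
#' @param s_bar Reference advantage in `(0, 1)`.
#' @param K Number of weights shown.
#' @return A ggplot object.
#' @export
plot_geometric_weights <- function(s_bar, K = 50L) {
  w <- geometric_weights(s_bar, K)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$k, y = .data$omega)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "generation k", y = expression(omega[k]),
                  title = sprintf("Geometric weights, reference advantage %.4g",
                                  s_bar))
}
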