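#' Fixation-probability result record
#'
#' Container for a fixation probability together with how it was obtained:
#' scalar fixed point, nested time-dependent iteration, a scenario closed
#' form, or Monte Carlo simulation (with a 99% confidence halfwidth).
#'
#' @param p Fixation probability in `[0, 1]`.
#' @param method One of `"fixed_point"`, `"nested"`, `"closed_form"`,
#'   `"monte_carlo"`.
#' @param iterations Iteration count, horizon, or replicate count.
#' @param ci_halfwidth Normal-approximation 99% CI halfwidth (Monte Carlo
#'   only).
#' @param ... Extra provenance fields stored alongside (e.g. `n_censored`).
#' @return A `fixation_result` object; `q = 1 - p` is stored with it.
#' @export
fixation_result <- function(p, method = c("fixed_point", "nested",
                                          "closed_form", "monte_carlo"),
                            iterations = NA_integer_,
                            ci_halfwidth = NA_real_, ...) {
  method <- match.arg(method)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single probability in [0, 1].",
          class = "gentimefix_domain_error")
  }
  structure(
    list(p = p, q = 1 - p, method = method,
         iterations = as.integer(iterations), ci_halfwidth = ci_halfwidth,
         ...),
    class = "fixation_result"
  )
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("<fixation_result> p = %.6g (q = %.6g), method = %s",
              x$p, x$q, x$method))
  if (!is.na(x$iterations)) cat(sprintf(", n = %d", x$iterations))
  if (!is.na(x$ci_halfwidth)) cat(sprintf(", 99%% CI +/- %.3g", x$ci_halfwidth))
  cat("\n")
  invisible(x)
}

#' @export
tidy.fixation_result <- function(x, ...) {
  tibble(p = x$p, q = x$q, method = x$method,
         iterations = x$iterations, ci_halfwidth = x$ci_halfwidth)
}

#' @export
glance.fixation_result <- function(x, ...) {
  tidy(x)
}
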