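# Probability-generating-function algebra for lineage models built from
# Poisson "growth" stages and binomial "sampling" (bottleneck) stages.

#' Poisson growth-stage PGF
#'
#' Generating function of a Poisson offspring distribution,
#' `exp(mean * (x - 1))`. One growth stage describes one round of
#' reproduction in a serial-passage lineage model.
#'
#' @param mean Positive mean offspring number (e.g. `2 * (1 + s)` for a
#'   fecundity mutant with wild-type mean 2).
#' @param x Evaluation point(s) in `[0, 1]`.
#' @param deriv `0` for the value, `1` for the first derivative
#'   `mean * exp(mean * (x - 1))`.
#' @return Numeric vector of PGF values (or derivatives) at `x`.
#' @examples
#' growth_pgf(2.1, 0)        # exp(-2.1)
#' growth_pgf(2, 1)          # 1: every PGF is 1 at 1
#' @export
growth_pgf <- function(mean, x, deriv = 0L) {
  if (!is.numeric(mean) || any(mean <= 0)) {
    abort("`mean` must be a positive offspring mean.", class = "gentimefix_domain_error")
  }
  check_unit_interval(x, "x")
  if (deriv == 0L) exp(mean * (x - 1)) else mean * exp(mean * (x - 1))
}

#' Binomial sampling-stage PGF
#'
#' Generating function of bottleneck thinning in which each individual
#' survives independently with probability `survival`:
#' `1 - survival + survival * x`. In a population of constant size whose
#' wild type has mean offspring `r`, the per-generation survival is `1 / r`.
#'
#' @param survival Survival probability in `(0, 1]`.
#' @param x Evaluation point(s) in `[0, 1]`.
#' @param deriv `0` for the value, `1` for the derivative (`survival`).
#' @return Numeric vector of PGF values (or derivatives) at `x`.
#' @examples
#' sampling_pgf(0.5, 0)      # 0.5
#' sampling_pgf(0.25, 0.6)   # 0.85
#' @export
sampling_pgf <- function(survival, x, deriv = 0L) {
  if (!is.numeric(survival) || any(survival <= 0) || any(survival > 1)) {
    abort("`survival` must lie in (0, 1].", class = "gentimefix_domain_error")
  }
  check_unit_interval(x, "x")
  if (deriv == 0L) 1 - survival + survival * x else rep(survival, length(x))
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1) || anyNA(x)) {
    abort(paste0("`", name, "` must lie in [0, 1]."),
          class = "gentimefix_domain_error")
  }
  invisible(x)
}

#' Single reproduction or sampling stage
#'
#' @param mean Positive Poisson mean for a growth stage.
#' @param survival Survival probability in `(0, 1]` for a sampling stage.
#' @return A `stage_pgf` object.
#' @examples
#' growth_stage(2)
#' sampling_stage(1 / 2)
#' @export
growth_stage <- function(mean) {
  growth_pgf(mean, 1)  # validates mean
  structure(list(kind = "growth", param = mean), class = "stage_pgf")
}

#' @rdname growth_stage
#' @export
sampling_stage <- function(survival) {
  sampling_pgf(survival, 1)  # validates survival
  structure(list(kind = "sampling", param = survival), class = "stage_pgf")
}

#' @export
print.stage_pgf <- function(x, ...) {
  lab <- if (x$kind == "growth") "Poisson growth, mean" else "binomial sampling, survival"
  cat(sprintf("<stage_pgf: %s %.6g>\n", lab, x$param))
  invisible(x)
}

#' Composite PGF of an ordered list of stages
#'
#' Stages are given in time order; the lineage PGF over the whole cycle is
#' the functional composition with the first stage outermost, so a
#' growth-then-sampling cycle evaluates as `y(z(x))` with the sampling stage
#' innermost.
#'
#' @param stages List of [growth_stage()] / [sampling_stage()] objects
#'   (bare numeric means are promoted to growth stages).
#' @return A `composite_pgf` object.
#' @examples
#' phi <- composite_pgf(list(growth_stage(2), sampling_stage(1 / 2)))
#' compose_cycle(phi, 0)   # exp(-1): Poisson(1) by the thinning identity
#' pgf_mean(phi)           # 1
#' @export
composite_pgf <- function(stages) {
  if (inherits(stages, "stage_pgf")) stages <- list(stages)
  if (!is.list(stages) || length(stages) == 0L) {
    abort("`stages` must be a nonempty list of stages.",
          class = "gentimefix_usage_error")
  }
  stages <- lapply(stages, function(st) {
    if (inherits(st, "stage_pgf")) st else growth_stage(st)
  })
  structure(list(stages = stages), class = "composite_pgf")
}

#' @export
print.composite_pgf <- function(x, ...) {
  kinds <- vapply(x$stages, `[[`, "", "kind")
  cat(sprintf("<composite_pgf: %d stages (%s), mean %.6g>\n",
              length(x$stages), paste(substr(kinds, 1, 1), collapse = ""),
              pgf_mean(x)))
  invisible(x)
}

stage_encoding <- function(pgf) {
  stages <- pgf$stages
  list(
    type = vapply(stages, function(s) if (s$kind == "growth") 0L else 1L, 0L),
    param = vapply(stages, `[[`, 0, "param")
  )
}

#' Evaluate a composite PGF
#'
#' Applies the stages right-to-left (innermost stage last in time order is
#' evaluated first).
#'
#' @param pgf A [composite_pgf()].
#' @param x Evaluation point(s) in `[0, 1]`.
#' @return Numeric vector of composite PGF values at `x`.
#' @export
compose_cycle <- function(pgf, x) {
  stopifnot(inherits(pgf, "composite_pgf"))
  check_unit_interval(x, "x")
  enc <- stage_encoding(pgf)
  vapply(x, function(xi) cpp_nested_stages(enc$type, enc$param, xi), 0)
}

#' Mean of a composite PGF
#'
#' Derivative at 1: the product of stage means (growth means and sampling
#' survival probabilities).
#'
#' @param pgf A [composite_pgf()] or [growth_stage()]/[sampling_stage()].
#' @return The mean offspring number of the composite.
#' @export
pgf_mean <- function(pgf) {
  if (inherits(pgf, "stage_pgf")) return(pgf$param)
  stopifnot(inherits(pgf, "composite_pgf"))
  prod(vapply(pgf$stages, `[[`, 0, "param"))
}

#' Extinction and fixation probability of a time-homogeneous lineage
#'
#' Iterates `x <- phi(x)` from `x = 0`; the limit is the extinction
#' probability `q`, the smallest root of `phi(x) = x`, and the fixation
#' probability is `p = 1 - q`. Subcritical or critical composites
#' (mean at most 1) are reported as `p = 0` without iterating.
#'
#' @param pgf A [composite_pgf()] (or a single stage).
#' @param tol Absolute convergence tolerance for the fixed-point iterate.
#' @param max_iter Maximum number of iterations.
#' @return A [fixation_result()] with `method = "fixed_point"`.
#' @examples
#' # fecundity mutant, r = 2, s = 0.05: 1 - p = exp(-1.05 * p)
#' phi <- composite_pgf(list(growth_stage(2 * 1.05), sampling_stage(1 / 2)))
#' extinction_probability(phi)$p
#' @export
extinction_probability <- function(pgf, tol = 1e-12, max_iter = 1e6L) {
  if (inherits(pgf, "stage_pgf")) pgf <- composite_pgf(list(pgf))
  stopifnot(inherits(pgf, "composite_pgf"), tol > 0)
  if (pgf_mean(pgf) <= 1 + 1e-12) {
    return(fixation_result(p = 0, method = "fixed_point", iterations = 0L))
  }
  enc <- stage_encoding(pgf)
  res <- cpp_fixed_point(enc$type, enc$param, tol, as.integer(max_iter))
  if (!res$converged) {
    abort(
      sprintf("Fixed-point iteration did not converge in %d iterations (last iterate %.15g).",
              res$iterations, res$q),
      class = "gentimefix_convergence_error", last_iterate = res$q
    )
  }
  fixation_result(p = 1 - res$q, method = "fixed_point",
                  iterations = res$iterations)
}

#' Fixation probability under a time-inhomogeneous environment
#'
#' Evaluates the nested extinction recursion
#' `q = lim_n phi_0(phi_1(... phi_n(0)))` by backward accumulation, doubling
#' the horizon until the fixation probability stabilises. The environment is
#' supplied as a generator `seq_fun(n)` returning the first `n` cycles
#' (a [stage_sequence][build_stage_sequence] or a list of composites).
#'
#' @param seq_fun Function of the horizon `n` returning a stage sequence, or
#'   a constant `composite_pgf` (reducing to [extinction_probability()]'s
#'   problem), or a numeric matrix generator for polynomial PGFs (rows =
#'   generations, columns = coefficients of `1, x, x^2, x^3`).
#' @param tol Stop when successive horizon doublings change `p` by less.
#' @param horizon_init,horizon_max Initial and maximal horizon (cycles).
#' @return A [fixation_result()] with `method = "nested"`; `iterations` is
#'   the final horizon.
#' @export
time_dependent_extinction <- function(seq_fun, tol = 1e-10,
                                      horizon_init = 1024L,
                                      horizon_max = 2^22) {
  stopifnot(tol > 0)
  if (inherits(seq_fun, "composite_pgf")) {
    pgf <- seq_fun
    seq_fun <- function(n) rep(list(pgf), n)
  }
  stopifnot(is.function(seq_fun))

  nested_q <- function(n) {
    obj <- seq_fun(n)
    if (inherits(obj, "stage_sequence")) {
      cpp_nested_stages(obj$stage_type, obj$stage_param, 0)
    } else if (is.matrix(obj)) {
      cpp_nested_poly(obj, 0)
    } else if (is.list(obj)) {
      enc_type <- integer(0)
      enc_param <- numeric(0)
      for (pgf in obj) {
        enc <- stage_encoding(pgf)
        enc_type <- c(enc_type, enc$type)
        enc_param <- c(enc_param, enc$param)
      }
      cpp_nested_stages(enc_type, enc_param, 0)
    } else {
      abort("Unsupported sequence type from `seq_fun`.",
            class = "gentimefix_usage_error")
    }
  }

  # Critical/subcritical guard: if the average log cycle mean is <= 0 the
  # process dies out and nested convergence is O(1/n), so report p = 0
  # outright. A short horizon can miss rare supercritical cycles (extra
  # generations under very small s), so an apparently critical prefix is
  # re-checked at a deep horizon before declaring extinction.
  if (mean_log_cycle_mean(seq_fun(as.integer(horizon_init))) <= 1e-12) {
    deep <- as.integer(min(horizon_max, 2^20))
    if (deep <= horizon_init ||
        mean_log_cycle_mean(seq_fun(deep)) <= 1e-12) {
      return(fixation_result(p = 0, method = "nested", iterations = 0L))
    }
  }

  n <- as.integer(horizon_init)
  p_prev <- 1 - nested_q(n)
  while (n < horizon_max) {
    n2 <- min(2L * n, as.integer(horizon_max))
    p_new <- 1 - nested_q(n2)
    if (abs(p_new - p_prev) < tol) {
      return(fixation_result(p = p_new, method = "nested", iterations = n2))
    }
    p_prev <- p_new
    n <- n2
  }
  abort(
    sprintf("Nested iteration not stabilised at horizon %d (p = %.10g) vs %d.",
            n, p_prev, n %/% 2L),
    class = "gentimefix_convergence_error", horizon = n, p_last = p_prev
  )
}

mean_log_cycle_mean <- function(obj) {
  if (inherits(obj, "stage_sequence")) {
    sum(log(obj$stage_param)) / obj$n_cycles
  } else if (is.matrix(obj)) {
    mean(log(obj[, 2] + 2 * obj[, 3] + 3 * obj[, 4]))
  } else {
    mean(vapply(obj, function(p) log(pgf_mean(p)), 0))
  }
}
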