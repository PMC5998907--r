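# Approximation-vs-exact comparison sweeps across the scenarios: for each
# grid point, the scenario closed form (or weighted-sum approximation), the
# exact nested iteration, and optionally a Monte Carlo estimate.

scenario_names <- c("constant", "monotone", "cyclic", "demography", "ar1")

# Per-generation trajectory function and approximation for one grid point.
scenario_components <- function(scenario, params, r = 2) {
  switch(scenario,
    constant = list(
      s_fun = function(k) rep(params$s, length(k)),
      s_bar = params$s,
      approx = function(mechanism) {
        fixation_approx(params$s, mechanism)
      }
    ),
    monotone = list(
      s_fun = function(k) monotone_selection(k, params$s0, params$s_inf),
      s_bar = params$s_inf,
      approx = function(mechanism) {
        s_e <- monotone_closed_form(params$s0, params$s_inf)$s_e
        fixation_approx(s_e, mechanism)
      }
    ),
    cyclic = list(
      s_fun = function(k) cyclic_selection(k, params$s_mean, params$delta_s,
                                           params$rho, params$theta),
      s_bar = params$s_mean,
      approx = function(mechanism) {
        s_e <- cyclic_closed_form(params$s_mean, params$delta_s,
                                  params$rho, params$theta)$s_e
        fixation_approx(s_e, mechanism)
      }
    ),
    demography = list(
      s_fun = function(k) demography_selection(k, params$s, params$n0,
                                               params$capacity,
                                               params$growth_rate),
      s_bar = params$s,
      survival_fun = function(n) demography_survival(n - 1, r, params$n0,
                                                     params$capacity,
                                                     params$growth_rate),
      approx = function(mechanism) {
        s_fun <- function(k) demography_selection(k, params$s, params$n0,
                                                  params$capacity,
                                                  params$growth_rate)
        fixation_approx(effective_advantage(s_fun, s_bar = params$s),
                        mechanism)
      }
    ),
    ar1 = {
      path <- ar1_trajectory(params$path_length %||% 4096L, params$s_mean,
                             params$lam, params$noise_sd, params$s0,
                             seed = params$seed)
      s_vec <- path$s
      list(
        s_fun = function(k) {
          ifelse(k < length(s_vec), s_vec[pmin(k + 1, length(s_vec))],
                 params$s_mean)
        },
        s_bar = params$s_mean,
        approx = function(mechanism) {
          s_e <- effective_advantage(
            function(k) ifelse(k < length(s_vec),
                               s_vec[pmin(k + 1, length(s_vec))],
                               params$s_mean),
            s_bar = params$s_mean)
          fixation_approx(s_e, mechanism)
        },
        path = path
      )
    },
    abort(sprintf("Unknown scenario '%s'.", scenario),
          class = "gentimefix_usage_error")
  )
}

#' Exact, approximate, and Monte Carlo fixation at one scenario point
#'
#' @param scenario One of `"constant"`, `"monotone"`, `"cyclic"`,
#'   `"demography"`, `"ar1"`.
#' @param params Named list of scenario parameters (`s`; `s0`, `s_inf`;
#'   `s_mean`, `delta_s`, `rho`, `theta`; `s`, `n0`, `capacity`,
#'   `growth_rate`; `s0`, `s_mean`, `lam`, `noise_sd`, `seed`).
#' @param mechanism `"generation_time"` or `"fecundity"`.
#' @param r Wild-type mean offspring number.
#' @param tau Bottleneck interval (per-generation trajectories require 1).
#' @param mc Optional list with `replicates`, `seed`, and optionally
#'   `establishment_threshold`, `max_cycles`, enabling the Monte Carlo
#'   column.
#' @param tol Stabilisation tolerance for the exact nested iteration.
#' @return One-row tibble: a comparison record.
#' @export
scenario_point <- function(scenario, params,
                           mechanism = c("generation_time", "fecundity"),
                           r = 2, tau = 1L, mc = NULL, tol = 1e-10) {
  mechanism <- match.arg(mechanism)
  scenario <- match.arg(scenario, scenario_names)
  if (scenario == "demography" && mechanism == "fecundity") {
    abort("Demography sweeps are defined for generation-time mutants only.",
          class = "gentimefix_usage_error")
  }
  comp <- scenario_components(scenario, params, r = r)

  p_approx <- comp$approx(mechanism)
  exact <- if (mechanism == "generation_time") {
    gentime_fixation_numeric(
      s = params$s, r = r, tau = tau,
      s_per_generation = if (scenario %in% c("constant", "demography")) NULL else comp$s_fun,
      survival_fun = comp$survival_fun, tol = tol
    )
  } else {
    fecundity_fixation_numeric(
      s = params$s, r = r, tau = tau,
      s_per_generation = if (scenario == "constant") NULL else comp$s_fun,
      tol = tol
    )
  }

  rec <- tibble(
    scenario = scenario, mechanism = mechanism,
    !!!params[vapply(params, is.numeric, TRUE)],
    p_exact = exact$p, p_approx = p_approx,
    rel_err = if (exact$p > 0) abs(p_approx - exact$p) / exact$p else NA_real_,
    converged = TRUE
  )
  if (!is.null(mc)) {
    seq_fun <- function(n) {
      surv <- if (is.null(comp$survival_fun)) NULL else comp$survival_fun(seq_len(n))
      build_stage_sequence(
        s = params$s, r = r, tau = tau, n_bottlenecks = n,
        s_per_generation = if (scenario %in% c("constant", "demography")) NULL else comp$s_fun,
        survival = surv
      )
    }
    sim <- monte_carlo_fixation(
      seq_fun,
      replicates = mc$replicates %||% 1e5,
      seed = mc$seed,
      establishment_threshold = mc$establishment_threshold %||% 1000L,
      max_cycles = mc$max_cycles %||% 5000L
    )
    rec$mc_estimate <- sim$p
    rec$mc_ci99 <- sim$ci_halfwidth
  }
  rec
}

#' Comparison sweep over a parameter grid
#'
#' Runs [scenario_point()] over the cross product of the supplied parameter
#' vectors and collects the comparison records; grid points failing to
#' converge are flagged (`converged = FALSE`) and the sweep continues.
#'
#' @inheritParams scenario_point
#' @param grid Named list of parameter vectors; the cross product is swept.
#' @return A `comparison_sweep` tibble sorted by the swept parameters, with
#'   attributes recording tolerance and Monte Carlo settings.
#' @examples
#' comparison_sweep("constant", list(s = c(0.005, 0.01)))
#' @export
comparison_sweep <- function(scenario, grid,
                             mechanism = c("generation_time", "fecundity"),
                             r = 2, tau = 1L, mc = NULL, tol = 1e-10) {
  mechanism <- match.arg(mechanism)
  scenario <- match.arg(scenario, scenario_names)
  pts <- tidyr::expand_grid(!!!grid)
  swept <- names(grid)[vapply(grid, function(v) length(unique(v)) > 1L, TRUE)]
  rows <- purrr::map(seq_len(nrow(pts)), function(i) {
    params <- as.list(pts[i, ])
    tryCatch(
      scenario_point(scenario, params, mechanism = mechanism, r = r,
                     tau = tau, mc = mc, tol = tol),
      gentimefix_convergence_error = function(e) {
        tibble(scenario = scenario, mechanism = mechanism, !!!params,
               p_exact = NA_real_, p_approx = NA_real_, rel_err = NA_real_,
               converged = FALSE)
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  if (length(swept) > 0L) out <- dplyr::arrange(out, !!!rlang::syms(swept))
  class(out) <- c("comparison_sweep", class(out))
  attr(out, "tol") <- tol
  attr(out, "mc") <- mc
  attr(out, "swept") <- swept
  out
}
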