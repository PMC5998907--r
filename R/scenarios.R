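# The four environmental scenarios: monotone selection, cyclic selection,
# Beverton-Holt demography, and AR(1) stochastic selection. Each provides a
# per-generation trajectory, a trajectory-tibble constructor carrying the
# analytic reference advantage, and (where one exists) the closed-form
# effective advantage and fixation approximation.

#' Monotonically increasing selection
#'
#' `s_k = s0 * exp(-k/2) + s_inf * (1 - exp(-k/2))`: the advantage relaxes
#' from `s0` to `s_inf` at a fixed rate 1/2 per generation.
#'
#' @param k 0-based generation index (vectorised).
#' @param s0 Initial advantage (>= 0).
#' @param s_inf Asymptotic advantage (> 0, small).
#' @return `s_k` values.
#' @export
monotone_selection <- function(k, s0, s_inf) {
  stopifnot(s0 >= 0, s_inf > 0)
  e <- exp(-k / 2)
  s0 * e + s_inf * (1 - e)
}

#' @rdname monotone_selection
#' @param n_generations Trajectory length.
#' @return For `monotone_trajectory()`, a [selection_trajectory()] with
#'   `s_bar = s_inf` (the Cesaro limit).
#' @export
monotone_trajectory <- function(n_generations, s0, s_inf) {
  s <- monotone_selection(seq_len(n_generations) - 1, s0, s_inf)
  selection_trajectory(s, s_bar = s_inf, source = "scenario")
}

#' Closed-form approximation for monotone selection
#'
#' Reference advantage `s_inf`; effective advantage
#' `s_e = s_inf * [1 + (s0 - s_inf) / (1 - e^{-1/2} (1 - s_inf))]` (the
#' geometric sum of the weighted trajectory in closed form); fixation
#' probability `s_e / ln 2`.
#'
#' @inheritParams monotone_selection
#' @return Tibble with columns `s_bar`, `s_e`, `p`.
#' @export
monotone_closed_form <- function(s0, s_inf) {
  stopifnot(s0 >= 0, s_inf > 0)
  s_e <- s_inf * (1 + (s0 - s_inf) / (1 - exp(-1 / 2) * (1 - s_inf)))
  p <- s_e / log(2)
  if (p <= 0 || p >= 1) {
    abort("Closed form outside (0, 1); parameters violate the small-s regime.",
          class = "gentimefix_domain_error")
  }
  tibble(s_bar = s_inf, s_e = s_e, p = p)
}

#' Cyclically changing selection
#'
#' `s_k = s_mean + delta_s * cos(k * rho + theta)` with angular frequency
#' `rho` (radians per generation) and phase `theta`.
#'
#' @param k 0-based generation index (vectorised).
#' @param s_mean Mean advantage (> 0).
#' @param delta_s Fluctuation amplitude (`< s_mean` keeps `s_k > 0`).
#' @param rho Angular frequency, radians per generation.
#' @param theta Phase, radians.
#' @return `s_k` values.
#' @export
cyclic_selection <- function(k, s_mean, delta_s, rho, theta) {
  stopifnot(s_mean > 0, delta_s >= 0, delta_s < s_mean)
  s_mean + delta_s * cos(k * rho + theta)
}

#' @rdname cyclic_selection
#' @param n_generations Trajectory length.
#' @export
cyclic_trajectory <- function(n_generations, s_mean, delta_s, rho, theta) {
  s <- cyclic_selection(seq_len(n_generations) - 1, s_mean, delta_s, rho, theta)
  selection_trajectory(s, s_bar = s_mean, source = "scenario")
}

#' Closed-form approximation for cyclic selection
#'
#' Reference advantage `s_mean`; the weighted cosine sum in closed form
#' gives
#' `s_e = s_mean * [1 + delta_s * ((1 - s_mean) cos(rho - theta) - cos(theta))
#'  / (2 (1 - s_mean) cos(rho) - (1 - s_mean)^2 - 1)]`.
#'
#' @inheritParams cyclic_selection
#' @return Tibble with columns `s_bar`, `s_e`, `p`.
#' @export
cyclic_closed_form <- function(s_mean, delta_s, rho, theta) {
  stopifnot(s_mean > 0, delta_s >= 0)
  denom <- 2 * (1 - s_mean) * cos(rho) - (1 - s_mean)^2 - 1
  if (abs(denom) < .Machine$double.eps) {
    abort("Degenerate parameters: zero denominator in the cyclic closed form.",
          class = "gentimefix_domain_error")
  }
  s_e <- s_mean *
    (1 + delta_s * ((1 - s_mean) * cos(rho - theta) - cos(theta)) / denom)
  tibble(s_bar = s_mean, s_e = s_e, p = s_e / log(2))
}

#' Beverton-Holt census trajectory
#'
#' `N_n = C N0 / (N0 + (C - N0) e^{-g n})`: density-regulated growth from
#' `N0` towards the carrying capacity `C` at rate `g`.
#'
#' @param n 0-based generation index (vectorised).
#' @param n0 Initial census size (> 0).
#' @param capacity Carrying capacity `C` (> 0).
#' @param growth_rate Growth rate `g`.
#' @return Census sizes `N_n`.
#' @export
beverton_holt <- function(n, n0, capacity, growth_rate) {
  stopifnot(n0 > 0, capacity > 0)
  capacity * n0 / (n0 + (capacity - n0) * exp(-growth_rate * n))
}

#' Per-generation advantage under changing population size
#'
#' With constant mutant advantage `s`, the mutant's net mean offspring in
#' generation `n` is `M_n = (N_{n+1}/N_n)(1 + s)`; the induced
#' per-generation advantage is `s_n = M_n - 1`, and the reference
#' environment is the stationary carrying-capacity regime, `s_bar = s`.
#' Generations where a shrinking census overwhelms `s` (`s_n <= 0`) are
#' outside the approximation's validity and trigger a warning.
#'
#' @inheritParams beverton_holt
#' @param s Constant mutant advantage (> 0).
#' @return `s_n` values.
#' @export
demography_selection <- function(n, s, n0, capacity, growth_rate) {
  stopifnot(s > 0)
  ratio <- beverton_holt(n + 1, n0, capacity, growth_rate) /
    beverton_holt(n, n0, capacity, growth_rate)
  s_n <- ratio * (1 + s) - 1
  if (any(s_n <= 0)) {
    warn("Some generations have s_n <= 0 (census decline overwhelms s); the approximation does not cover them.")
  }
  s_n
}

#' @rdname demography_selection
#' @param n_generations Trajectory length.
#' @export
demography_trajectory <- function(n_generations, s, n0, capacity, growth_rate) {
  s_n <- demography_selection(seq_len(n_generations) - 1, s, n0, capacity,
                              growth_rate)
  selection_trajectory(s_n, s_bar = s, source = "scenario")
}

# Wild-type sampling survival per generation under the census trajectory:
# N_{n+1} / (r N_n), so the wild-type net mean is the census ratio while
# the growth mean stays r.
demography_survival <- function(n, r, n0, capacity, growth_rate) {
  beverton_holt(n + 1, n0, capacity, growth_rate) /
    (r * beverton_holt(n, n0, capacity, growth_rate))
}

#' AR(1) stochastic selection path
#'
#' `s_k = (1 - lam) s_mean + lam s_{k-1} + xi_k` with white noise `xi_k`
#' of standard deviation `noise_sd` (Gaussian by default), conditioned on
#' `s_0 = s0`. Draws that would make `s_k <= 0` are clamped to `1e-6`; the
#' clamp count is reported as an attribute.
#'
#' @param n_generations Path length.
#' @param s_mean Mean advantage (> 0).
#' @param lam Correlation coefficient in `[0, 1]`.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param s0 Conditioning initial advantage (> 0).
#' @param seed Optional RNG seed; the current RNG stream is used (and left
#'   untouched) when a seed is given.
#' @return A [selection_trajectory()] with `s_bar = s_mean` and attributes
#'   `n_clamped`.
#' @export
ar1_trajectory <- function(n_generations, s_mean, lam, noise_sd, s0,
                           seed = NULL) {
  stopifnot(s_mean > 0, lam >= 0, lam <= 1, noise_sd >= 0, s0 > 0)
  draw <- function() {
    xi <- rnorm(n_generations - 1L, 0, noise_sd)
    s <- numeric(n_generations)
    s[1] <- s0
    for (k in 2:n_generations) {
      s[k] <- (1 - lam) * s_mean + lam * s[k - 1L] + xi[k - 1L]
    }
    s
  }
  s <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  n_clamped <- sum(s <= 0)
  s[s <= 0] <- 1e-6
  out <- selection_trajectory(s, s_bar = s_mean, source = "sampled")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Conditional mean and expected fixation under AR(1) selection
#'
#' Conditional mean `E[s_k | s0] = (1 - lam^k) s_mean + lam^k s0`; plugging
#' it into the geometric-weight average gives the expected fixation
#' probability
#' `E[p | s0] = (s_mean / ln 2) [1 + (s0 - s_mean) / (1 - lam (1 - s_mean))]`.
#'
#' @inheritParams ar1_trajectory
#' @param k 0-based generation index (vectorised).
#' @return `ar1_conditional_mean()`: `E[s_k | s0]`;
#'   `ar1_closed_form()`: tibble with `s_bar`, `s_e`, `p` (expected values).
#' @export
ar1_conditional_mean <- function(k, s0, s_mean, lam) {
  (1 - lam^k) * s_mean + lam^k * s0
}

#' @rdname ar1_conditional_mean
#' @export
ar1_closed_form <- function(s0, s_mean, lam) {
  stopifnot(s_mean > 0, lam >= 0, lam <= 1)
  s_e <- s_mean * (1 + (s0 - s_mean) / (1 - lam * (1 - s_mean)))
  tibble(s_bar = s_mean, s_e = s_e, p = s_e / log(2))
}
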