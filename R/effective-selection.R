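# The perturbation approximation: a changing environment is condensed into
# one number, the effective selective advantage s_e, a geometric-weight
# average of the per-generation advantages around a constant reference
# environment with advantage s_bar.

#' Selection trajectory
#'
#' A per-generation sequence of selective advantages as a tibble with
#' 0-based `generation` and `s` columns, carrying the reference advantage
#' `s_bar` as an attribute.
#'
#' @param s Numeric vector of per-generation advantages (positive; a zero
#'   is tolerated only as the initial value of a relaxing scenario).
#' @param s_bar Reference advantage; defaults to `mean(s)`.
#' @param source One of `"explicit"`, `"scenario"`, `"sampled"`.
#' @return A `selection_trajectory` tibble.
#' @export
selection_trajectory <- function(s, s_bar = NULL,
                                 source = c("explicit", "scenario", "sampled")) {
  source <- match.arg(source)
  if (!is.numeric(s) || length(s) == 0L || any(s < 0) || anyNA(s)) {
    abort("All trajectory values must be nonnegative.",
          class = "gentimefix_domain_error")
  }
  s_bar <- s_bar %||% mean(s)
  if (s_bar <= 0) {
    abort("`s_bar` must be positive.", class = "gentimefix_domain_error")
  }
  out <- tibble(generation = seq_along(s) - 1L, s = s)
  class(out) <- c("selection_trajectory", class(out))
  attr(out, "s_bar") <- s_bar
  attr(out, "source") <- source
  out
}

#' Reference advantage as a Cesaro mean
#'
#' Evaluates the running arithmetic mean of the trajectory at doubling
#' checkpoints and accepts once the relative change drops below `tol`.
#' Cesaro convergence is O(1/n), so tight tolerances need long horizons;
#' scenario constructors carry their analytic limits instead.
#'
#' @param trajectory A [selection_trajectory()], numeric vector, or
#'   vectorised function of the 0-based generation index.
#' @param tol Relative-change tolerance between checkpoints.
#' @param horizon Maximum number of generations examined (functions only).
#' @return The reference advantage `s_bar`.
#' @export
reference_advantage <- function(trajectory, tol = 1e-8, horizon = 1e6) {
  if (is.function(trajectory)) {
    s <- trajectory(seq_len(horizon) - 1)
  } else {
    s <- as_trajectory_values(trajectory)
  }
  n <- length(s)
  cm <- cumsum(s) / seq_len(n)
  checkpoints <- 2^(3:floor(log2(n)))
  if (length(checkpoints) >= 2L) {
    for (j in 2:length(checkpoints)) {
      m1 <- cm[checkpoints[j - 1L]]
      m2 <- cm[checkpoints[j]]
      if (abs(m2 - m1) <= tol * abs(m2)) return(cm[n])
    }
  }
  abort(
    sprintf("Cesaro mean not converged to rel. tol %g within %d generations (last mean %.10g).",
            tol, n, cm[n]),
    class = "gentimefix_convergence_error", last_mean = cm[n]
  )
}

#' Geometric weights of the effective-advantage average
#'
#' `omega_k = s_bar * (1 - s_bar)^k`: the weight of generation `k` in the
#' effective selective advantage. The weights sum to 1 over all k and decay
#' monotonically, so early generations dominate.
#'
#' @param s_bar Reference advantage in `(0, 1)`.
#' @param K Number of weights returned (k = 0, ..., K-1).
#' @return Tibble with columns `k`, `omega`; attribute `tail_mass` holds the
#'   untruncated remainder `(1 - s_bar)^K`.
#' @examples
#' geometric_weights(0.5, 3)   # 0.5, 0.25, 0.125; tail 0.125
#' @export
geometric_weights <- function(s_bar, K) {
  if (!is.numeric(s_bar) || length(s_bar) != 1L || s_bar <= 0 || s_bar >= 1) {
    abort("`s_bar` must lie in (0, 1).", class = "gentimefix_domain_error")
  }
  k <- seq_len(K) - 1L
  out <- tibble(k = k, omega = s_bar * (1 - s_bar)^k)
  attr(out, "tail_mass") <- (1 - s_bar)^K
  out
}

#' Truncation horizon of the geometric weights
#'
#' Smallest `K` with `(1 - s_bar)^K < tol`.
#'
#' @inheritParams geometric_weights
#' @param tol Tail-mass tolerance.
#' @return Integer horizon `K`.
#' @export
weight_horizon <- function(s_bar, tol = 1e-10) {
  as.integer(ceiling(log(tol) / log1p(-s_bar)))
}

#' Effective selective advantage
#'
#' The geometric-weight average `s_e = sum_k omega_k s_k`, truncated where
#' the tail mass times the largest advantage falls below `tol`.
#'
#' @param trajectory A [selection_trajectory()], numeric vector (0-indexed),
#'   or vectorised function of the 0-based generation index.
#' @param s_bar Reference advantage; taken from the trajectory attribute
#'   when absent.
#' @param tol Absolute truncation tolerance on `s_e`.
#' @return `s_e`, with attributes `K` (terms used) and `tail_mass`.
#' @export
effective_advantage <- function(trajectory, s_bar = NULL, tol = 1e-10) {
  s_bar <- s_bar %||% attr(trajectory, "s_bar")
  if (is.null(s_bar)) {
    abort("Supply `s_bar` or a trajectory carrying one.",
          class = "gentimefix_usage_error")
  }
  K <- weight_horizon(s_bar, tol)
  if (is.function(trajectory)) {
    s <- trajectory(seq_len(K) - 1)
  } else {
    s <- as_trajectory_values(trajectory)
    if (length(s) < K) {
      abort(
        sprintf("Trajectory has %d generations but truncation needs %d; build it at least `weight_horizon(s_bar, tol)` long.",
                length(s), K),
        class = "gentimefix_usage_error"
      )
    }
    s <- s[seq_len(K)]
  }
  # refine K so the neglected tail is below tol even for large advantages
  smax <- max(abs(s))
  if (smax > 1) {
    K2 <- weight_horizon(s_bar, tol / smax)
    if (K2 > K) {
      return(effective_advantage(trajectory, s_bar = s_bar, tol = tol / smax))
    }
  }
  w <- s_bar * (1 - s_bar)^(seq_len(K) - 1L)
  se <- sum(w * s)
  attr(se, "K") <- K
  attr(se, "tail_mass") <- (1 - s_bar)^K
  se
}

#' First-order fixation approximation from the effective advantage
#'
#' `p = s_e / ln 2` for generation-time mutants, `p = 2 s_e` for fecundity
#' mutants; their ratio is `2 ln 2` for any `s_e`.
#'
#' @param s_e Effective selective advantage (> 0, small).
#' @param mechanism `"generation_time"` or `"fecundity"`.
#' @return The approximate fixation probability.
#' @examples
#' fixation_approx(0.01, "generation_time")   # 0.01 / log(2)
#' fixation_approx(0.01, "fecundity")         # 0.02
#' @export
fixation_approx <- function(s_e, mechanism = c("generation_time", "fecundity")) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(s_e) || any(s_e <= 0)) {
    abort("`s_e` must be positive.", class = "gentimefix_domain_error")
  }
  p <- if (mechanism == "generation_time") s_e / log(2) else 2 * s_e
  if (any(p >= 1)) {
    abort("Approximation invalid: implied fixation probability >= 1.",
          class = "gentimefix_domain_error")
  }
  as.numeric(p)
}

#' First-order perturbation series for the fixation probability
#'
#' Expansion around the reference environment:
#' `p = p_bar + p_bar * sum_k (s_k - s_bar) sigma^k` with decay factor
#' `sigma = 1 - s_bar`. With that sigma the centred form is algebraically
#' identical to the direct form `p_bar * sum_k s_k (1 - s_bar)^k`, and both
#' equal `fixation_approx(effective_advantage(...), "generation_time")`
#' when `p_bar = s_bar / ln 2`.
#'
#' @inheritParams effective_advantage
#' @param p_bar Reference fixation probability; defaults to
#'   `s_bar / ln 2` (the small-s closed form). Pass a numerically computed
#'   reference instead for sensitivity checks.
#' @param sigma Geometric decay factor; defaults to `1 - s_bar`.
#' @param form `"centred"` (expansion form) or `"direct"` (rearranged
#'   geometric form).
#' @return Approximate fixation probability.
#' @export
perturbation_series <- function(trajectory, s_bar = NULL, p_bar = NULL,
                                sigma = NULL, tol = 1e-10,
                                form = c("centred", "direct")) {
  form <- match.arg(form)
  s_bar <- s_bar %||% attr(trajectory, "s_bar")
  if (is.null(s_bar)) {
    abort("Supply `s_bar` or a trajectory carrying one.",
          class = "gentimefix_usage_error")
  }
  p_bar <- p_bar %||% (s_bar / log(2))
  sigma <- sigma %||% (1 - s_bar)
  if (sigma <= 0 || sigma >= 1) {
    abort("`sigma` must lie in (0, 1).", class = "gentimefix_domain_error")
  }
  K <- max(weight_horizon(s_bar, tol),
           as.integer(ceiling(log(tol) / log(sigma))))
  if (is.function(trajectory)) {
    s <- trajectory(seq_len(K) - 1)
  } else {
    s <- as_trajectory_values(trajectory)
    if (length(s) < K) {
      abort(sprintf("Trajectory has %d generations but the series needs %d.",
                    length(s), K),
            class = "gentimefix_usage_error")
    }
    s <- s[seq_len(K)]
  }
  pw <- sigma^(seq_len(K) - 1L)
  if (form == "centred") {
    p_bar + p_bar * sum((s - s_bar) * pw)
  } else {
    p_bar * sum(s * pw)
  }
}
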