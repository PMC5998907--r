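# Machinery specific to "generation time" mutants: a mutant that produces
# the wild-type offspring number (mean r) but completes its generations in a
# fraction t_g = 1/(1 + s_tilde) of a wild-type generation. Its advantage is
# realised purely through extra growth generations that fit between
# bottlenecks.

#' Scaled selective advantage of a generation-time mutant
#'
#' `s_tilde = log_r(1 + s)`: the per-generation surplus in completed mutant
#' generations per wild-type generation that makes the mutant's total growth
#' equal that of a fecundity mutant with advantage `s`. For small `s` this is
#' approximately `s / ln(r)`.
#'
#' @param s Selective advantage (> -1; beneficial mutants have `s > 0`).
#' @param r Wild-type mean offspring number (> 1, default 2 for binary
#'   fission).
#' @return `log(1 + s) / log(r)`, vectorised over `s`.
#' @examples
#' scaled_advantage(0.05, 2)   # log2(1.05)
#' @export
scaled_advantage <- function(s, r = 2) {
  if (!is.numeric(s) || any(s <= -1)) {
    abort("`s` must exceed -1.", class = "gentimefix_domain_error")
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 1) {
    abort("`r` must exceed 1.", class = "gentimefix_domain_error")
  }
  log1p(s) / log(r)
}

#' Generation time of a mutant in wild-type units
#'
#' @param s_tilde Scaled advantage ([scaled_advantage()]), nonnegative.
#' @return `1 / (1 + s_tilde)`, in `(0, 1]`.
#' @examples
#' generation_time_of(1 / 20)  # 20/21
#' @export
generation_time_of <- function(s_tilde) {
  if (!is.numeric(s_tilde) || any(s_tilde < 0)) {
    abort("`s_tilde` must be nonnegative (deleterious generation-time mutants are out of scope).",
          class = "gentimefix_domain_error")
  }
  1 / (1 + s_tilde)
}

#' Extra-generation schedule under constant selection
#'
#' The i-th extra mutant generation first fits before bottleneck
#' `n_i = ceiling(i / (s_tilde * tau))`: the smallest bottleneck count at
#' which `(n_i * tau + i)` mutant generations of length `1/(1 + s_tilde)`
#' complete within `n_i * tau` wild-type generations. The inequality is
#' non-strict, so exact integer ratios are attained.
#'
#' @param s_tilde Scaled advantage (> 0).
#' @param tau Bottleneck interval in wild-type generations (>= 1).
#' @param n_bottlenecks Horizon: schedule entries with `n_i` at most this.
#' @return A tibble with columns `i` (extra-generation index) and
#'   `bottleneck` (`n_i`), with attributes `s_tilde` and `t_g`.
#' @examples
#' extra_generation_schedule(1 / 20, 5, 8)  # n_1 = 4, n_2 = 8
#' @export
extra_generation_schedule <- function(s_tilde, tau, n_bottlenecks) {
  if (!is.numeric(s_tilde) || length(s_tilde) != 1L || s_tilde <= 0 ||
      tau < 1 || n_bottlenecks < 1) {
    abort("Need s_tilde > 0, tau >= 1, n_bottlenecks >= 1.",
          class = "gentimefix_domain_error")
  }
  i_max <- floor(n_bottlenecks * s_tilde * tau + 1e-9)
  i <- seq_len(i_max)
  n_i <- as.integer(ceiling(i / (s_tilde * tau) - 1e-9))
  n_i <- n_i[n_i <= n_bottlenecks]
  out <- tibble(i = i[seq_along(n_i)], bottleneck = n_i)
  attr(out, "s_tilde") <- s_tilde
  attr(out, "t_g") <- generation_time_of(s_tilde)
  out
}

# Per-cycle extra-generation counts from a per-generation scaled-advantage
# trajectory: the cumulative sum A_T = sum_{k<T} s_tilde_k counts completed
# surplus mutant generations; an extra growth stage is inserted each time
# floor(A) increments. For constant s this reproduces n_i = ceil(i/(s~ tau))
# exactly.
extra_counts_from_strajectory <- function(s_tilde_per_gen, tau, n_bottlenecks) {
  a <- cumsum(s_tilde_per_gen)
  ends <- seq_len(n_bottlenecks) * tau
  extras_by_cycle <- floor(a[ends] + 1e-9)
  as.integer(diff(c(0, extras_by_cycle)))
}

#' Build the per-cycle stage sequence of a generation-time mutant
#'
#' Each bottleneck cycle is `tau` Poisson growth stages of mean `r` followed
#' by one sampling stage of survival `r^-tau` (so the wild-type composite
#' mean is 1 per cycle); cycles hosting a scheduled extra mutant generation
#' get one additional growth stage (`phi+` cycles). Under a per-generation
#' selection trajectory the extra stages are placed by accumulating the
#' scaled advantage `log_r(1 + s_k)` and inserting one stage per completed
#' unit; with constant `s` this reduces exactly to the
#' [extra_generation_schedule()].
#'
#' @param s Constant selective advantage (ignored when `s_per_generation`
#'   is supplied).
#' @param r Wild-type mean offspring number.
#' @param tau Bottleneck interval in wild-type generations.
#' @param n_bottlenecks Number of cycles to build.
#' @param s_per_generation Optional per-generation trajectory: a numeric
#'   vector (0-indexed generations, length at least `n_bottlenecks * tau`)
#'   or a vectorised function of the 0-based generation index.
#' @param survival Optional per-cycle sampling survival overriding
#'   `r^-tau` (used for changing population sizes).
#' @return A `stage_sequence` object.
#' @examples
#' seq8 <- build_stage_sequence(s = 2^(1 / 20) - 1, tau = 5, n_bottlenecks = 8)
#' cycle_pattern(seq8)  # phi phi phi phi+ phi phi phi phi+
#' @export
build_stage_sequence <- function(s = NULL, r = 2, tau = 1L, n_bottlenecks,
                                 s_per_generation = NULL, survival = NULL) {
  tau <- as.integer(tau)
  n_bottlenecks <- as.integer(n_bottlenecks)
  if (n_bottlenecks < 1L || tau < 1L) {
    abort("Need n_bottlenecks >= 1 and tau >= 1.",
          class = "gentimefix_domain_error")
  }
  if (is.null(s_per_generation)) {
    if (is.null(s) || s < 0) {
      abort("Supply a nonnegative constant `s` or a trajectory.",
            class = "gentimefix_domain_error")
    }
    st <- rep(scaled_advantage(s, r), n_bottlenecks * tau)
  } else {
    sk <- resolve_trajectory(s_per_generation, n_bottlenecks * tau)
    if (any(sk < 0) || anyNA(sk)) {
      abort("All trajectory values must be nonnegative.",
            class = "gentimefix_domain_error")
    }
    st <- scaled_advantage(sk, r)
  }
  extra <- extra_counts_from_strajectory(st, tau, n_bottlenecks)
  surv <- if (is.null(survival)) rep(r^(-tau), n_bottlenecks) else {
    stopifnot(length(survival) == n_bottlenecks)
    survival
  }
  new_stage_sequence(growth_counts = tau + extra, growth_mean = r,
                     survivals = surv, r = r, tau = tau,
                     extra_counts = extra)
}

# Flat stage encoding: one sampling stage closes each cycle.
new_stage_sequence <- function(growth_counts, growth_mean, survivals, r, tau,
                               extra_counts = NULL) {
  n <- length(growth_counts)
  growth_mean <- rep_len(growth_mean, n)
  counts <- growth_counts + 1L
  total <- sum(counts)
  ends <- cumsum(counts)
  type <- integer(total)
  type[ends] <- 1L
  param <- numeric(total)
  param[type == 0L] <- rep.int(growth_mean, growth_counts)
  param[ends] <- survivals
  structure(
    list(n_cycles = n, r = r, tau = tau,
         growth_counts = as.integer(growth_counts),
         growth_mean = growth_mean, survivals = survivals,
         extra_counts = extra_counts,
         stage_type = type, stage_param = param),
    class = "stage_sequence"
  )
}

#' @export
print.stage_sequence <- function(x, ...) {
  cat(sprintf("<stage_sequence: %d cycles, tau = %d, r = %g, %d extra stages>\n",
              x$n_cycles, x$tau, x$r,
              if (is.null(x$extra_counts)) NA_integer_ else sum(x$extra_counts)))
  invisible(x)
}

#' @export
length.stage_sequence <- function(x) x$n_cycles

#' Cycle pattern of a stage sequence
#'
#' @param seq A `stage_sequence`.
#' @return Character vector, one entry per cycle: `"phi"` for a plain cycle,
#'   `"phi+"` for a cycle carrying one extra growth stage (more `+` for
#'   more).
#' @export
cycle_pattern <- function(seq) {
  stopifnot(inherits(seq, "stage_sequence"))
  extra <- seq$growth_counts - seq$tau
  paste0("phi", strrep("+", pmax(extra, 0L)))
}

#' Convert a stage sequence to a list of composite PGFs
#'
#' @param seq A `stage_sequence`.
#' @return List of [composite_pgf()] objects, one per cycle in time order.
#' @export
as_composite_list <- function(seq) {
  stopifnot(inherits(seq, "stage_sequence"))
  lapply(seq_len(seq$n_cycles), function(c) {
    stages <- c(
      replicate(seq$growth_counts[c], growth_stage(seq$growth_mean[c]),
                simplify = FALSE),
      list(sampling_stage(seq$survivals[c]))
    )
    composite_pgf(stages)
  })
}

# Accept a vector (recycled past its end with its reference value) or a
# vectorised function of the 0-based generation index.
resolve_trajectory <- function(s_per_generation, n_generations) {
  if (is.function(s_per_generation)) {
    return(s_per_generation(seq_len(n_generations) - 1))
  }
  s <- as_trajectory_values(s_per_generation)
  if (length(s) >= n_generations) return(s[seq_len(n_generations)])
  fill <- attr(s_per_generation, "s_bar") %||% s[length(s)]
  c(s, rep(fill, n_generations - length(s)))
}

as_trajectory_values <- function(x) {
  if (inherits(x, "selection_trajectory") || is.data.frame(x)) x$s else as.numeric(x)
}

#' Exact fixation probability of a generation-time mutant
#'
#' Builds the extra-generation stage sequence and runs the nested
#' time-dependent extinction recursion (which reduces to the scalar fixed
#' point when the environment is constant and the cycle pattern periodic).
#'
#' @inheritParams build_stage_sequence
#' @param tol Stabilisation tolerance on `p` between horizon doublings.
#' @param horizon_init,horizon_max Initial/maximal horizon in cycles.
#' @param survival_fun Optional function of the 1-based cycle index vector
#'   returning per-cycle sampling survivals (changing population sizes).
#' @return A [fixation_result()].
#' @examples
#' gentime_fixation_numeric(s = 0.01)$p       # close to 0.01 / log(2)
#' @export
gentime_fixation_numeric <- function(s = NULL, r = 2, tau = 1L,
                                     s_per_generation = NULL, tol = 1e-10,
                                     horizon_init = 1024L,
                                     horizon_max = 2^22, survival_fun = NULL) {
  seq_fun <- function(n) {
    surv <- if (is.null(survival_fun)) NULL else survival_fun(seq_len(n))
    build_stage_sequence(s = s, r = r, tau = tau, n_bottlenecks = n,
                         s_per_generation = s_per_generation,
                         survival = surv)
  }
  time_dependent_extinction(seq_fun, tol = tol, horizon_init = horizon_init,
                            horizon_max = horizon_max)
}

#' Exact fixation probability of a fecundity mutant
#'
#' A fecundity mutant has Poisson mean `r*(1+s)` per growth stage. In a
#' constant environment the per-cycle composite collapses (Poisson thinning)
#' and the scalar fixed point applies; for a per-generation trajectory
#' (bottleneck interval 1) each generation is Poisson with mean `1 + s_k`.
#'
#' @inheritParams gentime_fixation_numeric
#' @return A [fixation_result()].
#' @examples
#' fecundity_fixation_numeric(s = 0.05)$p     # about 0.0907
#' @export
fecundity_fixation_numeric <- function(s = NULL, r = 2, tau = 1L,
                                       s_per_generation = NULL, tol = 1e-10,
                                       horizon_init = 1024L,
                                       horizon_max = 2^22) {
  tau <- as.integer(tau)
  if (is.null(s_per_generation)) {
    stages <- c(replicate(tau, growth_stage(r * (1 + s)), simplify = FALSE),
                list(sampling_stage(r^(-tau))))
    return(extinction_probability(composite_pgf(stages), tol = min(tol, 1e-12)))
  }
  if (tau != 1L) {
    abort("Variable-environment fecundity sequences are supported for tau = 1 only.",
          class = "gentimefix_usage_error")
  }
  seq_fun <- function(n) {
    sk <- resolve_trajectory(s_per_generation, n)
    new_stage_sequence(growth_counts = rep(1L, n), growth_mean = 1 + sk,
                       survivals = rep(1, n), r = r, tau = 1L)
  }
  time_dependent_extinction(seq_fun, tol = tol, horizon_init = horizon_init,
                            horizon_max = horizon_max)
}
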