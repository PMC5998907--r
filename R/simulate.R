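# Monte Carlo lineage simulator: the independent oracle. Replicate lineages
# start from one mutant; growth stages draw Poisson offspring (a cohort of
# size n under mean m collapses to one Poisson(n m) draw), sampling stages
# binomial-thin. A replicate counts as surviving once it reaches the
# establishment threshold; conditional on that many copies, eventual loss is
# negligible for the advantages considered, so the survival fraction is a
# fixation-probability estimate.

#' Monte Carlo fixation probability of a lineage
#'
#' @param stage_seq A [stage_sequence][build_stage_sequence] covering at
#'   least `max_cycles` cycles, or a function of `n` cycles returning one.
#' @param replicates Number of independent lineages.
#' @param seed Optional RNG seed (current stream used, and restored, when
#'   given).
#' @param establishment_threshold Lineage size declaring survival
#'   (at least 100).
#' @param max_cycles Cycle cap; lineages still alive at the cap are counted
#'   as survived and reported in the `n_censored` field with a warning.
#' @return A [fixation_result()] with `method = "monte_carlo"`, the
#'   normal-approximation 99% CI halfwidth, and `n_censored`.
#' @examples
#' seq1 <- build_stage_sequence(s = 0.05, n_bottlenecks = 3000)
#' monte_carlo_fixation(seq1, replicates = 2000, seed = 1, max_cycles = 3000)
#' @export
monte_carlo_fixation <- function(stage_seq, replicates = 1e5, seed = NULL,
                                 establishment_threshold = 1000L,
                                 max_cycles = 5000L) {
  if (establishment_threshold < 100L || replicates < 1L) {
    abort("Need establishment_threshold >= 100 and replicates >= 1.",
          class = "gentimefix_domain_error")
  }
  if (is.function(stage_seq)) stage_seq <- stage_seq(max_cycles)
  stopifnot(inherits(stage_seq, "stage_sequence"))
  max_cycles <- min(as.integer(max_cycles), stage_seq$n_cycles)

  run <- function() {
    sizes <- rep.int(1L, replicates)
    survived <- 0L
    censored <- 0L
    for (cyc in seq_len(max_cycles)) {
      n_alive <- length(sizes)
      if (n_alive == 0L) break
      g <- stage_seq$growth_counts[cyc]
      m <- stage_seq$growth_mean[cyc]
      for (j in seq_len(g)) sizes <- rpois(n_alive, m * sizes)
      sizes <- rbinom(n_alive, sizes, stage_seq$survivals[cyc])
      est <- sizes >= establishment_threshold
      survived <- survived + sum(est)
      sizes <- sizes[!est & sizes > 0L]
    }
    censored <- length(sizes)
    list(survived = survived + censored, censored = censored)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (res$censored > 0L) {
    warn(sprintf("%d lineages were still alive below threshold at max_cycles; counted as survived.",
                 res$censored))
  }
  p_hat <- res$survived / replicates
  ci <- qnorm(0.995) * sqrt(p_hat * (1 - p_hat) / replicates)
  fixation_result(p = p_hat, method = "monte_carlo",
                  iterations = as.integer(replicates), ci_halfwidth = ci,
                  n_censored = res$censored)
}
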