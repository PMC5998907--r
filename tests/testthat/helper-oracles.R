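# Independent oracles used across the suite.

# Scalar fixed-point oracle: smallest positive root of 1 - p = phi(1 - p),
# located by root bracketing (independent of the package's iteration).
bisect_fixation <- function(phi, upper = 0.999, tol = 1e-13) {
  f <- function(p) phi(1 - p) - (1 - p)
  stats::uniroot(f, c(1e-9, upper), tol = tol)$root
}

# Direct truncated geometric-weight sum; the closed forms must agree with it.
direct_weighted_sum <- function(s_fun, s_bar, K) {
  k <- 0:(K - 1)
  sum(s_bar * (1 - s_bar)^k * s_fun(k))
}

# Brute-force extra-generation schedule: smallest n with
# (n * tau + i) / (1 + s_tilde) <= n * tau, by exhaustive search.
brute_schedule <- function(s_tilde, tau, n_max) {
  out <- integer(0)
  i <- 1L
  repeat {
    hit <- NA_integer_
    for (n in seq_len(n_max)) {
      if ((n * tau + i) / (1 + s_tilde) <= n * tau + 1e-9) {
        hit <- n
        break
      }
    }
    if (is.na(hit)) break
    out[i] <- hit
    i <- i + 1L
  }
  out
}
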