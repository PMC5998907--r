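test_that("monotone selection interpolates from s0 to s_inf", {
  expect_equal(monotone_selection(0, 0.002, 0.01), 0.002)
  expect_equal(monotone_selection(1e3, 0.002, 0.01), 0.01)
  expect_equal(monotone_selection(0:50, 0.01, 0.01), rep(0.01, 51))
  tr <- monotone_trajectory(100, 0.001, 0.01)
  expect_equal(attr(tr, "s_bar"), 0.01)
  expect_true(all(diff(tr$s) >= 0))          # exp(-k/2) underflows far out
  expect_true(all(diff(tr$s[1:20]) > 0))
})

test_that("monotone closed form collapses for a flat environment", {
  cf <- monotone_closed_form(0.01, 0.01)
  expect_equal(cf$s_bar, 0.01)
  expect_equal(cf$s_e, 0.01)
  expect_equal(cf$p, 0.01 / log(2))
})

test_that("cyclic selection has the stated phase, amplitude and period", {
  expect_equal(cyclic_selection(0:20, 0.01, 0, 0.3, 1), rep(0.01, 21))
  expect_equal(cyclic_selection(0, 0.01, 0.005, 0.3, pi), 0.005)
  rho <- 2 * pi / 8
  s <- cyclic_selection(0:31, 0.01, 0.004, rho, 0.7)
  expect_equal(s[1:8], s[9:16])
})

test_that("cyclic closed form reduces to the constant limit as rho -> 0", {
  expect_equal(cyclic_closed_form(0.01, 0, 0.3, 1)$p, 0.01 / log(2))
  # rho -> 0, theta = 0: the trajectory is the constant s_mean + delta_s
  cf <- cyclic_closed_form(0.01, 0.004, 1e-9, 0)
  s_const <- effective_advantage(function(k) rep(0.014, length(k)),
                                 s_bar = 0.01)
  expect_equal(cf$s_e, as.numeric(s_const), tolerance = 1e-6)
})

test_that("Beverton-Holt census has the right endpoints and fixed point", {
  expect_equal(beverton_holt(0, 500, 1e4, 0.01), 500)
  expect_equal(beverton_holt(0:100, 1e4, 1e4, 0.05), rep(1e4, 101))
  expect_equal(beverton_holt(1e5, 300, 1e4, 0.01), 1e4, tolerance = 1e-6)
})

test_that("demography maps census change onto per-generation advantage", {
  expect_equal(demography_selection(0:50, 0.01, 1e4, 1e4, 0.02),
               rep(0.01, 51))
  expect_equal(demography_selection(1e5, 0.01, 1e3, 1e4, 0.01), 0.01,
               tolerance = 1e-6)
  # growing census boosts the early advantage
  s_n <- demography_selection(0:10, 0.01, 1e3, 1e4, 0.01)
  expect_true(all(s_n > 0.01))
  # shrinking census can overwhelm a small advantage
  expect_warning(demography_selection(0:10, 0.001, 5e4, 1e4, 0.05))
})

test_that("AR(1) paths: degenerate limits, reproducibility, clamping", {
  expect_equal(ar1_trajectory(10, 0.02, 1, 0, 0.005)$s, rep(0.005, 10))
  expect_equal(ar1_trajectory(10, 0.02, 0, 0, 0.005)$s,
               c(0.005, rep(0.02, 9)))
  a <- ar1_trajectory(200, 0.02, 0.6, 0.001, 0.001, seed = 5)
  b <- ar1_trajectory(200, 0.02, 0.6, 0.001, 0.001, seed = 5)
  expect_identical(a$s, b$s)
  # violent noise gets clamped to a positive floor, and the events counted
  cl <- ar1_trajectory(500, 0.001, 0.2, 0.05, 0.001, seed = 9)
  expect_gt(attr(cl, "n_clamped"), 0)
  expect_true(all(cl$s > 0))
})

test_that("AR(1) long-run sample mean approaches s_mean", {
  withr::with_seed(31, {
    finals <- replicate(1000, {
      tail(ar1_trajectory(200, 0.02, 0.6, 0.001, 0.001)$s, 1)
    })
  })
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.02), 3 * se + 1e-5)
})

test_that("AR(1) conditional mean and expected fixation closed forms", {
  expect_equal(ar1_conditional_mean(0:20, 0.02, 0.02, 0.6), rep(0.02, 21))
  expect_equal(ar1_conditional_mean(1e3, 0.003, 0.02, 0.6), 0.02)
  expect_equal(ar1_closed_form(0.02, 0.02, 0.6)$p, 0.02 / log(2))

  # expected closed form equals the weighted sum of conditional means
  pars <- list(s0 = 0.001, s_mean = 0.02, lam = 0.6)
  direct <- direct_weighted_sum(
    function(k) ar1_conditional_mean(k, pars$s0, pars$s_mean, pars$lam),
    pars$s_mean, weight_horizon(pars$s_mean, 1e-14)
  )
  expect_equal(ar1_closed_form(pars$s0, pars$s_mean, pars$lam)$s_e, direct,
               tolerance = 1e-12)
})

test_that("path-wise first-order estimates average to the AR(1) closed form", {
  pars <- list(s0 = 0.001, s_mean = 0.02, lam = 0.6, sd = 0.001)
  n_paths <- 1e4
  K <- weight_horizon(pars$s_mean, 1e-8)
  p_bar <- pars$s_mean / log(2)
  w <- (1 - pars$s_mean)^(0:(K - 1))
  withr::with_seed(17, {
    # vectorised cohort of AR(1) recursions (same process as ar1_trajectory)
    s <- matrix(0, nrow = n_paths, ncol = K)
    s[, 1] <- pars$s0
    for (k in 2:K) {
      s[, k] <- (1 - pars$lam) * pars$s_mean + pars$lam * s[, k - 1] +
        rnorm(n_paths, 0, pars$sd)
    }
  })
  s[s <= 0] <- 1e-6
  p_paths <- p_bar + p_bar * as.numeric((s - pars$s_mean) %*% w)
  ci99 <- qnorm(0.995) * stats::sd(p_paths) / sqrt(n_paths)
  expected <- ar1_closed_form(pars$s0, pars$s_mean, pars$lam)$p
  expect_lt(abs(mean(p_paths) - expected), ci99 + 1e-6)
})

test_that("the approximation underestimates p after a deep early deficit", {
  s_fun <- function(k) ifelse(k < 50, 1e-4, 0.02)
  p_exact <- gentime_fixation_numeric(s_per_generation = s_fun)$p
  p_approx <- perturbation_series(s_fun, s_bar = 0.02)
  expect_lt(p_approx, p_exact)
})
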