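test_that("selection trajectories validate and carry their reference", {
  tr <- selection_trajectory(c(0.01, 0.02, 0.03))
  expect_s3_class(tr, "selection_trajectory")
  expect_equal(tr$generation, 0:2)
  expect_equal(attr(tr, "s_bar"), 0.02)
  expect_error(selection_trajectory(c(0.01, -0.01)),
               class = "gentimefix_domain_error")
  expect_error(selection_trajectory(0.01, s_bar = -1),
               class = "gentimefix_domain_error")
})

test_that("Cesaro reference converges for constants and errors when slow", {
  expect_equal(reference_advantage(rep(0.017, 64)), 0.017)
  # O(1/n) Cesaro convergence cannot meet a tight tolerance on a short path
  s_fun <- function(k) cyclic_selection(k, 0.01, 0.005, pi / 10, 0)
  expect_error(reference_advantage(s_fun, tol = 1e-12, horizon = 4096),
               class = "gentimefix_convergence_error")
  # a loose tolerance accepts the running mean near s_mean
  expect_equal(reference_advantage(s_fun, tol = 1e-3, horizon = 2^16), 0.01,
               tolerance = 1e-2)
})

test_that("geometric weights are a normalised, monotone-decaying distribution", {
  w <- geometric_weights(0.5, 3)
  expect_equal(w$omega, c(0.5, 0.25, 0.125))
  expect_equal(attr(w, "tail_mass"), 0.125)

  for (s_bar in c(0.001, 0.01, 0.2, 0.9)) {
    K <- weight_horizon(s_bar, 1e-12)
    w <- geometric_weights(s_bar, K)
    expect_lt(attr(w, "tail_mass"), 1e-12)
    expect_equal(sum(w$omega) + attr(w, "tail_mass"), 1, tolerance = 1e-14)
    expect_true(all(diff(w$omega) < 0))
  }
  expect_error(geometric_weights(1.2, 5), class = "gentimefix_domain_error")
})

test_that("effective advantage is the truncated weighted average", {
  # constant trajectory: weights sum to 1, so s_e = s_bar
  expect_equal(as.numeric(effective_advantage(function(k) rep(0.02, length(k)),
                                              s_bar = 0.02)),
               0.02, tolerance = 1e-10)

  # values beyond the truncation horizon do not matter at tolerance tol
  s_bar <- 0.05
  K <- weight_horizon(s_bar, 1e-10)
  base <- function(k) 0.05 + 0.01 * sin(k / 7)
  bumped <- function(k) ifelse(k >= K, 0.9, base(k))
  expect_equal(as.numeric(effective_advantage(base, s_bar = s_bar)),
               as.numeric(effective_advantage(bumped, s_bar = s_bar)),
               tolerance = 1e-8)

  # a too-short explicit trajectory is refused, not silently padded
  expect_error(effective_advantage(selection_trajectory(rep(0.01, 10))),
               class = "gentimefix_usage_error")
})

test_that("first-order fixation formulas and their 2 ln 2 ratio", {
  expect_equal(fixation_approx(0.01, "generation_time"), 0.01 / log(2))
  expect_equal(fixation_approx(0.01, "fecundity"), 0.02)
  for (s_e in c(1e-4, 1e-3, 1e-2)) {
    expect_equal(fixation_approx(s_e, "fecundity") /
                   fixation_approx(s_e, "generation_time"), 2 * log(2))
  }
  expect_error(fixation_approx(0.8, "fecundity"),
               class = "gentimefix_domain_error")
  expect_error(fixation_approx(-0.1), class = "gentimefix_domain_error")
})

test_that("perturbation series: both algebraic forms agree and reduce right", {
  s_bar <- 0.01
  p_bar <- s_bar / log(2)
  # flat environment: every disturbance vanishes
  expect_equal(perturbation_series(function(k) rep(s_bar, length(k)),
                                   s_bar = s_bar), p_bar, tolerance = 1e-10)

  s_fun <- function(k) monotone_selection(k, 0.001, 0.01)
  centred <- perturbation_series(s_fun, s_bar = s_bar, form = "centred")
  direct <- perturbation_series(s_fun, s_bar = s_bar, form = "direct")
  # forms differ only by the truncated geometric tail, p_bar * sigma^K
  expect_lt(abs(centred - direct), 1e-10)

  # and both equal the effective-advantage route
  p_via_se <- fixation_approx(effective_advantage(s_fun, s_bar = s_bar),
                              "generation_time")
  expect_lt(abs(centred - p_via_se), 1e-10)
})

test_that("closed-form effective advantages equal direct weighted sums", {
  # relaxing selection
  s0 <- 0; s_inf <- 0.01
  K <- weight_horizon(s_inf, 1e-14)
  cf <- monotone_closed_form(s0, s_inf)
  expect_equal(cf$s_e,
               direct_weighted_sum(function(k) monotone_selection(k, s0, s_inf),
                                   s_inf, K),
               tolerance = 1e-12)

  # seasonal selection
  pars <- list(s_mean = 0.01, delta_s = 0.005, rho = pi / 10, theta = pi)
  cf2 <- cyclic_closed_form(pars$s_mean, pars$delta_s, pars$rho, pars$theta)
  expect_equal(cf2$s_e,
               direct_weighted_sum(function(k) {
                 cyclic_selection(k, pars$s_mean, pars$delta_s, pars$rho,
                                  pars$theta)
               }, pars$s_mean, weight_horizon(pars$s_mean, 1e-14)),
               tolerance = 1e-12)
})

test_that("first-order error shrinks ~4x when the amplitude halves", {
  rs <- remainder_scaling(
    function(e) function(k) monotone_selection(k, 0.01 - e, 0.01),
    eps = 0.009, s_bar = 0.01
  )
  factor <- rs$abs_err[1] / rs$abs_err[2]
  expect_gt(factor, 3)
  expect_lt(factor, 5)
})
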