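test_that("critical lineages die out: survival fraction shrinks with horizon", {
  seq_fun <- function(n) build_stage_sequence(s = 0, n_bottlenecks = n)
  short <- suppressWarnings(
    monte_carlo_fixation(seq_fun, replicates = 5e3, seed = 3,
                         max_cycles = 100L))
  long <- suppressWarnings(
    monte_carlo_fixation(seq_fun, replicates = 5e3, seed = 3,
                         max_cycles = 2000L))
  expect_lte(long$p, short$p)
  expect_lt(long$p, 0.02)
})

test_that("Monte Carlo agrees with the fixed point for a fecundity mutant", {
  p_exact <- extinction_probability(
    composite_pgf(list(growth_stage(2.1), sampling_stage(0.5))))$p
  seq_fun <- function(n) {
    sk <- rep(0.05, n)
    # per-generation Poisson(1 + s) cycles via the thinning identity
    gentimefix:::new_stage_sequence(growth_counts = rep(1L, n),
                                    growth_mean = 1 + sk,
                                    survivals = rep(1, n), r = 2, tau = 1L)
  }
  mc <- monte_carlo_fixation(seq_fun, replicates = 5e4, seed = 13,
                             max_cycles = 2000L)
  expect_lt(abs(mc$p - p_exact), mc$ci_halfwidth)
})

test_that("Monte Carlo matches s/ln 2 for a small generation-time mutant", {
  s <- 0.02
  p_ref <- gentime_fixation_numeric(s = s)$p
  mc <- monte_carlo_fixation(
    function(n) build_stage_sequence(s = s, n_bottlenecks = n),
    replicates = 5e4, seed = 29)
  expect_lt(abs(mc$p - p_ref), mc$ci_halfwidth)
  expect_lt(abs(mc$p - s / log(2)), 2 * mc$ci_halfwidth)
})

test_that("identical seeds give identical simulations", {
  seq_fun <- function(n) build_stage_sequence(s = 0.02, n_bottlenecks = n)
  a <- monte_carlo_fixation(seq_fun, replicates = 1e4, seed = 7)
  b <- monte_carlo_fixation(seq_fun, replicates = 1e4, seed = 7)
  expect_identical(a$p, b$p)
})

test_that("simulator rejects invalid specs", {
  seq1 <- build_stage_sequence(s = 0.02, n_bottlenecks = 10)
  expect_error(monte_carlo_fixation(seq1, establishment_threshold = 10L),
               class = "gentimefix_domain_error")
  expect_error(monte_carlo_fixation(seq1, replicates = 0),
               class = "gentimefix_domain_error")
})

test_that("comparison sweeps cover the grid and flag convergence failures", {
  sw <- comparison_sweep("constant", list(s = c(1e-3, 5e-3, 1e-2)))
  expect_s3_class(sw, "comparison_sweep")
  expect_equal(nrow(sw), 3L)
  expect_true(all(sw$converged))
  expect_equal(sw$rel_err, abs(sw$p_approx - sw$p_exact) / sw$p_exact)
  # relative error vanishes with s: both limits are s / ln 2
  expect_lt(sw$rel_err[1], sw$rel_err[3])
})

test_that("approximation stays within 10% where fluctuations are perturbative", {
  recs <- dplyr::bind_rows(
    comparison_sweep("constant", list(s = c(0.001, 0.01, 0.02))),
    comparison_sweep("monotone", list(s0 = c(0, 0.001), s_inf = c(0.005, 0.02))),
    comparison_sweep("cyclic", list(s_mean = c(0.01, 0.02), delta_s = 0.005,
                                    rho = pi / 10, theta = pi)),
    comparison_sweep("demography", list(s = c(0.01, 0.02), n0 = 1e3,
                                        capacity = 1e4, growth_rate = 0.01)),
    comparison_sweep("ar1", list(s0 = 0.001, s_mean = 0.02, lam = 0.6,
                                 noise_sd = 0.001, seed = 11))
  )
  expect_true(all(recs$converged))
  expect_true(all(recs$rel_err <= 0.1))
})

test_that("demography with s well below g leaves the perturbative regime", {
  # census growth contributes fluctuations of order g; when the intrinsic
  # advantage is much smaller, the first-order result underestimates p
  rec <- scenario_point("demography", list(s = 0.001, n0 = 1e3,
                                           capacity = 1e4, growth_rate = 0.01))
  expect_lt(rec$p_approx, rec$p_exact)
  expect_gt(rec$rel_err, 0.1)
})

test_that("config runner reproduces library calls and writes stable CSV", {
  out_dir <- withr::local_tempdir()
  cfg <- list(sweeps = list(list(
    name = "tiny", scenario = "constant",
    grid = list(s = c(0.005, 0.01)),
    mc = list(replicates = 5e3, seed = 41)
  )))
  cfg_path <- file.path(out_dir, "cfg.yaml")
  yaml::write_yaml(cfg, cfg_path)

  res <- run_config(cfg_path, out_dir = out_dir)
  csv_path <- file.path(out_dir, "tiny.csv")
  expect_true(file.exists(csv_path))
  expect_true(file.exists(file.path(out_dir, "tiny.json")))

  direct <- comparison_sweep("constant", list(s = c(0.005, 0.01)),
                             mc = list(replicates = 5e3, seed = 41))
  expect_equal(as.data.frame(res$tiny), as.data.frame(direct))

  # byte-identical rerun under the same seed and config
  first <- readLines(csv_path)
  run_config(cfg_path, out_dir = out_dir)
  expect_identical(readLines(csv_path), first)
})

test_that("malformed configs fail with a field-level message", {
  out_dir <- withr::local_tempdir()
  bad <- list(sweeps = list(list(
    name = "bad", scenario = "constant", grid = list(s = c(-0.01, 0.01))
  )))
  path <- file.path(out_dir, "bad.yaml")
  yaml::write_yaml(bad, path)
  expect_error(run_config(path, out_dir = out_dir), regexp = "grid\\$s",
               class = "gentimefix_config_error")

  nos <- list(sweeps = list(list(name = "x", grid = list(s = 0.01))))
  path2 <- file.path(out_dir, "nos.yaml")
  yaml::write_yaml(nos, path2)
  expect_error(run_config(path2, out_dir = out_dir), regexp = "scenario",
               class = "gentimefix_config_error")
})

test_that("result records tidy into one-row tibbles", {
  fr <- gentime_fixation_numeric(s = 0.01)
  td <- tidy(fr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$p + td$q, 1)
  expect_named(glance(fr), names(td))
})

test_that("trajectory and sweep autoplots build without error", {
  tr <- monotone_trajectory(100, 0.001, 0.01)
  expect_s3_class(autoplot(tr), "ggplot")
  sw <- comparison_sweep("constant", list(s = c(0.005, 0.01)))
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(plot_geometric_weights(0.02), "ggplot")
})
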