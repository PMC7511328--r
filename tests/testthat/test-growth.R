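test_that("interval rates follow the log-ratio formula", {
  cu <- growth_curve(strain = "s", medium = "LB", replicate = 1,
                     times = seq(0, 3, by = 0.5),
                     od = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4))
  ir <- interval_rates(cu)
  expect_equal(nrow(ir), 6L)
  expect_equal(ir$mu[1], log(2) / 0.5, tolerance = 1e-12)
  expect_true(all(abs(ir$mu - log(2) / 0.5) < 1e-12))

  flat <- growth_curve(strain = "s", medium = "LB", replicate = 1,
                       times = 0:6, od = rep(0.5, 7))
  expect_true(all(interval_rates(flat)$mu == 0))
})

test_that("noiseless exponentials are recovered exactly on any grid", {
  for (mu in c(0.3, 0.8, 1.2)) {
    for (times in list(seq(0, 6, by = 0.25), seq(0, 12, by = 0.5),
                       cumsum(c(0, runif(20, 0.1, 0.9))))) {
      cu <- exp_curve(mu, times = times)
      ir <- interval_rates(cu)
      expect_true(all(abs(ir$mu[ir$valid] - mu) < 1e-11))
      est <- estimate_growth_rate(cu)
      expect_false(est$no_growth)
      expect_lt(abs(est$mu - mu) / mu, 1e-9)
    }
  }
})

test_that("estimator is invariant to positive scaling of the OD values", {
  set.seed(11)
  times <- seq(0, 8, by = 0.25)
  od <- 0.01 * exp(0.9 * times) * exp(rnorm(length(times), 0, 0.02))
  c1 <- growth_curve("s", "LB", 1, times = times, od = od)
  c2 <- growth_curve("s", "LB", 1, times = times, od = 7.3 * od)
  expect_equal(estimate_growth_rate(c1)$mu, estimate_growth_rate(c2)$mu,
               tolerance = 1e-12)
})

test_that("window selection matches exhaustive search on noisy curves", {
  set.seed(21)
  for (i in 1:25) {
    times <- seq(0, 10, by = 0.5)
    mu <- runif(1, 0.3, 1.3)
    od <- 0.01 * exp(mu * pmin(times, runif(1, 4, 8))) *
      exp(rnorm(length(times), 0, 0.05))
    cu <- growth_curve("s", "LB", 1, times = times, od = od)
    ir <- interval_rates(cu)
    oracle <- brute_force_window(ir$mu, ir$valid)
    est <- estimate_growth_rate(cu)
    expect_equal(est$window_start_index, oracle$start)
    expect_equal(est$mu, oracle$mean, tolerance = 1e-12)
  }
})

test_that("lag-exponential-plateau curves are scored inside the exponential segment", {
  times <- seq(0, 12, by = 0.5)
  od <- ifelse(times < 3, 0.01,
        ifelse(times < 8, 0.01 * exp(1.0 * (times - 3)),
               0.01 * exp(1.0 * 5)))
  cu <- growth_curve("s", "LB", 1, times = times, od = od)
  est <- estimate_growth_rate(cu)
  ir <- interval_rates(cu)
  oracle <- brute_force_window(ir$mu, ir$valid)
  expect_equal(est$mu, 1.0, tolerance = 1e-9)
  expect_equal(est$window_start_index, oracle$start)
  # whole selected window lies in the exponential phase (intervals 7..16)
  expect_gte(est$window_start_index, 7L)
  expect_lte(est$window_start_index + 4L, 16L)
})

test_that("logistic curves underestimate mu and converge as OD0/K shrinks", {
  mu <- 1.1
  est_big <- estimate_growth_rate(logistic_curve(mu, K = 1, od0 = 0.05))
  expect_lt(est_big$mu, mu)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(frac) {
    est <- estimate_growth_rate(logistic_curve(mu, K = 10, od0 = frac * 10,
                                               times = seq(0, 30, by = 0.25)))
    abs(est$mu - mu)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 1e-2)
})

test_that("curves below the positivity floor flag no growth", {
  cu <- growth_curve("s", "LB", 1, times = 0:8,
                     od = rep(0.081, 9), blank = 0.08)
  est <- estimate_growth_rate(cu)
  expect_true(est$no_growth)
  expect_true(is.na(est$mu))
})

test_that("replicate aggregation computes means and standard errors", {
  est <- do.call(rbind, lapply(1:3, function(r)
    estimate_growth_rate(exp_curve(c(1.0, 1.2, 1.4)[r], replicate = r))))
  rt <- aggregate_replicates(est)
  expect_equal(rt$mean_mu, 1.2, tolerance = 1e-9)
  expect_equal(rt$se_mu, sd(c(1.0, 1.2, 1.4)) / sqrt(3), tolerance = 1e-9)
  expect_equal(rt$n, 3L)

  single <- aggregate_replicates(est[1, ])
  expect_equal(single$se_mu, 0)
  expect_true(single$degenerate_n)

  dead <- estimate_growth_rate(growth_curve("dead", "LB", 1, times = 0:8,
                                            od = rep(0.08, 9), blank = 0.08))
  rt2 <- aggregate_replicates(rbind(est, dead))
  expect_false("dead" %in% rt2$strain)
  expect_equal(attr(rt2, "no_growth_strains")$strain, "dead")
})

test_that("carrying-capacity bias shows in max OD but not in the rate", {
  # positionally flat truth so wells and genome coordinates stay unconfounded
  cfg <- synthetic_config(n_genes = 192, essential_fraction = 0,
                          n_replicates = 1, well_bias_slope = 0.005,
                          od_sd = 0, growth_replicate_sd = 0,
                          positional_amplitude_growth = 0, target_rho = 0,
                          interval_h = 0.25, seed = 5)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, "LB")
  tr <- generate_growth_truth(ann, ex, cfg, "LB")
  pl <- generate_plate_curves(tr, cfg)
  est <- estimate_growth_rates(pl$curves)
  diag <- well_bias_diagnostic(est)
  expect_equal(diag$trend$rho[diag$trend$quantity == "max_od"], 1,
               tolerance = 1e-9)
  expect_lt(abs(diag$trend$rho[diag$trend$quantity == "mu"]), 0.2)
  # max OD strictly increasing in serpentine index within one plate
  p1 <- est[est$plate == 1, ]
  ord <- order(serpentine_index(p1$well))
  expect_true(all(diff(p1$max_od[ord]) > 0))
})

test_that("single-well input has no defined well trend", {
  est <- estimate_growth_rates(list(exp_curve(1.0, strain = "a"),
                                    exp_curve(1.1, strain = "b")))
  expect_error(well_bias_diagnostic(est), "single well")
})

test_that("rate vs growth-maximum correlation behaves under coupling and shuffling", {
  set.seed(31)
  n <- 300
  mu <- runif(n, 0.5, 1.5)
  rt <- rate_table_from(mu, max_od = 0.5 + 0.4 * mu + rnorm(n, 0, 0.05))
  res <- rate_vs_max_correlation(rt, "LB")
  expect_gt(res$rho, 0.5)
  expect_lt(res$p, 0.05)
  rt_shuf <- rate_table_from(mu, max_od = sample(rt$mean_max_od))
  expect_lt(abs(rate_vs_max_correlation(rt_shuf, "LB")$rho), 0.15)
  expect_error(rate_vs_max_correlation(rate_table_from(c(1, 2)), "LB"),
               ">= 3")
})
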