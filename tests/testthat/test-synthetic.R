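test_that("generation is deterministic given the config seed", {
  cfg <- synthetic_config(n_genes = 120, seed = 7)
  a1 <- generate_annotation(cfg); a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  e1 <- generate_expression(a1, cfg, "LB")
  e2 <- generate_expression(a2, cfg, "LB")
  expect_identical(e1, e2)
  t1 <- generate_growth_truth(a1, e1, cfg, "LB")
  t2 <- generate_growth_truth(a2, e2, cfg, "LB")
  expect_identical(t1, t2)
  p1 <- generate_plate_curves(t1, cfg); p2 <- generate_plate_curves(t2, cfg)
  expect_identical(p1, p2)
})

test_that("annotation respects the essentiality fraction and placement limits", {
  cfg0 <- synthetic_config(n_genes = 4, essential_fraction = 0,
                           genome_length_kb = 100, seed = 2)
  a0 <- generate_annotation(cfg0)
  expect_equal(nrow(a0), 4L)
  expect_true(all(a0$essential == 0L))
  expect_true(all(a0$midpoint_kb >= 0 & a0$midpoint_kb < 100))

  cfg <- synthetic_config(n_genes = 4000, essential_fraction = 0.07, seed = 3)
  ann <- generate_annotation(cfg)
  ci <- qbinom(c(0.005, 0.995), 4000, 0.07)   # binomial 99% interval
  expect_gte(sum(ann$essential), ci[1])
  expect_lte(sum(ann$essential), ci[2])

  expect_error(generate_annotation(
    synthetic_config(n_genes = 5000, genome_length_kb = 100)),
    "placement failure")
})

test_that("noise-free expression equals baseline plus deterministic parts", {
  cfg <- synthetic_config(n_genes = 50, positional_amplitude_expr = 0,
                          expression_sd = 0, gene_effect_sd = 0, seed = 4)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, "LB")
  expect_true(all(abs(ex$rep1 - cfg$baseline_expr) < 1e-12))
  expect_identical(ex$rep1, ex$rep3)
})

test_that("the expression positional component survives window smoothing", {
  cfg <- synthetic_config(n_genes = 4000, essential_fraction = 0,
                          positional_amplitude_expr = 0.3,
                          expression_sd = 0, gene_effect_sd = 0, seed = 5)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, "LB")
  sig <- positional_signal(ann, setNames(ex$mean, ex$gene),
                           cfg$genome_length_kb, mode = "nonessential_only")
  dom <- dominant_period(sig)
  expect_equal(dom$k, 6L)
  expect_equal(dom$wavelength, 772)
  N <- cfg$genome_length_kb; W <- 100; k <- 6
  atten <- abs(sin(pi * k * W / N) / (W * sin(pi * k / N)))
  # gene midpoints are binned to 1 kb before averaging, so allow a few
  # percent around the closed-form moving-average attenuation
  expect_lt(abs(dom$fit$amplitude - 0.3 * atten) / (0.3 * atten), 0.05)
})

test_that("growth-truth calibration hits the target correlation", {
  # exact anti-monotone limit
  cfg1 <- synthetic_config(n_genes = 100, target_rho = -1,
                           positional_amplitude_growth = 0,
                           growth_residual_sd = 0, seed = 6)
  ann1 <- generate_annotation(cfg1)
  ex1 <- generate_expression(ann1, cfg1, "LB")
  tr1 <- generate_growth_truth(ann1, ex1, cfg1, "LB")
  ne <- tr1$essential == 0
  expect_equal(cor(ex1$mean[ne], tr1$mu_true[ne], method = "spearman"), -1)

  # null case
  cfg0 <- synthetic_config(n_genes = 1000, target_rho = 0, seed = 6)
  ann0 <- generate_annotation(cfg0)
  ex0 <- generate_expression(ann0, cfg0, "LB")
  tr0 <- generate_growth_truth(ann0, ex0, cfg0, "LB")
  expect_lt(abs(attr(tr0, "realized_rho")), 0.05)

  # calibration contract across seeds at n >= 2000
  for (s in 1:10) {
    cfg <- synthetic_config(n_genes = 2000, target_rho = -0.37, seed = s)
    ann <- generate_annotation(cfg)
    ex <- generate_expression(ann, cfg, "M63")
    tr <- generate_growth_truth(ann, ex, cfg, "M63")
    expect_lt(abs(attr(tr, "realized_rho") - (-0.37)), 0.05)
  }
})

test_that("an unreachable target correlation raises a calibration error", {
  # constant expression leaves nothing to couple the growth rates to
  cfg <- synthetic_config(n_genes = 300, target_rho = -0.9,
                          positional_amplitude_expr = 0,
                          gene_effect_sd = 0, expression_sd = 0,
                          positional_amplitude_growth = 0,
                          growth_residual_sd = 0.05, seed = 8)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, "LB")
  expect_error(generate_growth_truth(ann, ex, cfg, "LB"),
               "calibration failure.*feasible range")
})

test_that("growth and expression positional components are in antiphase", {
  cfg <- synthetic_config(n_genes = 3000, essential_fraction = 0,
                          expression_sd = 0, growth_residual_sd = 0,
                          target_rho = -0.37, seed = 9)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, "LB")
  tr <- generate_growth_truth(ann, ex, cfg, "LB")
  L <- cfg$genome_length_kb
  se <- positional_signal(ann, setNames(attr(ex, "positional"), ex$gene), L,
                          mode = "nonessential_only")
  sg <- positional_signal(ann, setNames(attr(tr, "positional"), tr$gene), L,
                          mode = "nonessential_only")
  expect_lte(cor(se$values, sg$values), -0.95)
  # the realized growth series itself runs against the expression series
  sm <- positional_signal(ann, setNames(tr$mu_true, tr$gene), L,
                          mode = "nonessential_only")
  expect_lt(cor(se$values, sm$values), 0)
})

test_that("plate curves have the configured grid, bias, and rate structure", {
  cfg <- synthetic_config(n_genes = 60, essential_fraction = 0,
                          od_sd = 0, growth_replicate_sd = 0,
                          well_bias_slope = 0.004,
                          interval_h = 0.5, duration_h = 24, seed = 10)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, "LB")
  tr <- generate_growth_truth(ann, ex, cfg, "LB")
  pl <- generate_plate_curves(tr, cfg)
  expect_length(pl$curves, 60 * 3)
  expect_length(pl$curves[[1]]$times, 49L)   # 30-min grid over 24 h
  # replicates of one strain sit in different wells
  wm <- pl$well_map
  for (s in unique(wm$strain)[1:5])
    expect_equal(anyDuplicated(wm$well[wm$strain == s]), 0L)
  # carrying capacity increases with the serpentine well index, rates do not
  est <- estimate_growth_rates(pl$curves)
  idx <- serpentine_index(est$well)
  expect_gt(cor(est$max_od, idx, method = "spearman"), 0.95)
  expect_lt(abs(cor(est$mu, idx, method = "spearman")), 0.25)

  bad <- pl$well_map[c(1, 1), c("strain", "replicate", "plate", "well")]
  expect_error(generate_plate_curves(tr, cfg, layout = bad),
               "same well twice")
})

test_that("a noise-free early-exponential well recovers its true rate", {
  cfg <- synthetic_config(n_genes = 10, essential_fraction = 0, od_sd = 0,
                          growth_replicate_sd = 0, growth_residual_sd = 0,
                          positional_amplitude_growth = 0, target_rho = 0,
                          gene_effect_sd = 0, expression_sd = 0,
                          well_bias_slope = 0, od0 = 0.003,
                          media = list(LB = list(mu = 1.0, K = 30)),
                          duration_h = 30, seed = 11)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, "LB")
  tr <- generate_growth_truth(ann, ex, cfg, "LB")
  expect_true(all(abs(tr$mu_true - 1.0) < 1e-9))
  pl <- generate_plate_curves(tr, cfg)
  est <- estimate_growth_rates(pl$curves)
  expect_true(all(abs(est$mu - 1.0) < 1e-3))   # OD << K in the window
})
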