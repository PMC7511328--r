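test_that("positional signal averages per-gene values over circular windows", {
  L <- 500
  ann <- annotation_at(c(10.5, 210.5, 410.5), L)
  sig <- positional_signal(ann, setNames(rep(1, 3), ann$gene), L,
                           mode = "nonessential_only")
  expect_true(all(sig$values == 1))
  expect_equal(length(sig$values), 500L)

  # one gene at 10.5 kb: it falls in windows [a, a+100) with a in (p-100, p]
  one <- annotation_at(10.5, L)
  s1 <- positional_signal(one, setNames(5, one$gene), L,
                          mode = "nonessential_only")
  covered <- c(0:10, 411:499)          # circular wrap upstream of the gene
  expect_true(all(!s1$filled[covered + 1]))
  expect_true(all(s1$filled[setdiff(0:499, covered) + 1]))
  expect_true(all(s1$values == 5))     # fill = global mean of non-empty
})

test_that("signal modes handle essential genes as specified", {
  L <- 200
  ann <- annotation_at(c(50.5, 150.5), L, essential = c(1L, 0L))
  vals <- setNames(c(0.9, 0.4), ann$gene)   # essential gene has a recorded mu
  sz <- positional_signal(ann, vals, L, mode = "essential_zero")
  # every 100-kb window holds exactly one gene here; windows holding the
  # essential gene contribute 0 (not its recorded 0.9), the rest 0.4
  ess_windows <- c(0:50, 151:199) + 1
  expect_true(all(sz$values[ess_windows] == 0))
  expect_true(all(sz$values[-ess_windows] == 0.4))
  ne <- positional_signal(ann, vals, L, mode = "nonessential_only")
  expect_true(all(ne$values == 0.4))
  dens <- positional_signal(ann[ann$essential == 1L, , drop = FALSE],
                            genome_length_kb = L, mode = "density")
  expect_equal(sum(dens$values), 100)   # one gene in 100 windows of the 200
})

test_that("periodogram places all power at the harmonic of a pure cosine", {
  a <- 0:4631
  pg <- periodogram(cos(2 * pi * 6 * a / 4632), genome_length_kb = 4632)
  expect_equal(pg$k[which.max(pg$power)], 6L)
  expect_equal(pg$wavelength[which.max(pg$power)], 772)
  expect_lt(sum(pg$power[-6]) / pg$power[6], 1e-12)

  expect_true(periodogram(rep(3, 100), genome_length_kb = 100)$constant)

  two <- 2 * cos(2 * pi * 3 * a / 4632) + cos(2 * pi * 9 * a / 4632)
  pg2 <- periodogram(two, genome_length_kb = 4632)
  expect_equal(pg2$power[3] / pg2$power[9], 4, tolerance = 1e-9)
  expect_equal(pg2$k[which.max(pg2$power)], 3L)
})

test_that("the power scaling satisfies Parseval's identity", {
  set.seed(71)
  for (N in c(100, 4632)) {
    x <- rnorm(N)
    pg <- periodogram(x, genome_length_kb = N)
    xd <- x - mean(x)
    lhs <- 2 * sum(pg$power) - (N %% 2 == 0) * pg$power[N %/% 2]
    expect_equal(lhs, sum(xd^2), tolerance = 1e-9)
  }
})

test_that("circular rotation changes the phase but not the spectrum", {
  set.seed(72)
  x <- as.numeric(smooth_circular(rnorm(600), 50))
  shift <- 123
  y <- c(x[(shift + 1):600], x[1:shift])
  pa <- periodogram(x, genome_length_kb = 600)
  pb <- periodogram(y, genome_length_kb = 600)
  expect_equal(pa$power, pb$power, tolerance = 1e-9)
  ga <- fisher_g_test(pa); gb <- fisher_g_test(pb)
  expect_equal(ga$g, gb$g, tolerance = 1e-12)
  da <- dominant_period(x); db <- dominant_period(y)
  expect_equal(da$k, db$k)
  expect_false(isTRUE(all.equal(da$fit$phase, db$fit$phase)))
})

test_that("100-kb smoothing attenuates a harmonic by the Dirichlet factor", {
  N <- 4632; W <- 100
  for (k in c(1, 2, 6, 7, 20)) {
    x <- cos(2 * pi * k * (0:(N - 1)) / N)
    sm <- smooth_circular(x, W)
    measured <- fit_sinusoid(sm, k)$amplitude
    closed <- abs(sin(pi * k * W / N) / (W * sin(pi * k / N)))
    expect_lt(abs(measured - closed), 1e-6)
  }
})

test_that("Fisher's g limits match the closed form", {
  p1 <- fisher_g_test(c(0, 0, 1, 0, 0))
  expect_equal(p1$g, 1)
  expect_equal(p1$p, 0)
  p2 <- fisher_g_test(c(0.5, 0.5))
  expect_equal(p2$g, 0.5)
  expect_equal(p2$p, 1)
  expect_error(fisher_g_test(c(0, 0, 0)), "all-zero")
})

test_that("Fisher's g null rejection rate is calibrated", {
  set.seed(73)
  rej <- mean(replicate(1000, {
    pg <- periodogram(rnorm(500), genome_length_kb = 500)
    fisher_g_test(pg)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("sinusoid fitting recovers amplitude, phase, and offset", {
  N <- 1000
  x <- 1.7 + 0.6 * cos(2 * pi * 4 * (0:(N - 1)) / N + 0.9)
  f <- fit_sinusoid(x, 4)
  expect_equal(f$amplitude, 0.6, tolerance = 1e-9)
  expect_equal(f$phase, 0.9, tolerance = 1e-9)
  expect_equal(f$offset, 1.7, tolerance = 1e-9)
  expect_lt(f$rss, 1e-18)
  expect_lt(fit_sinusoid(x, 7)$amplitude, 1e-12)  # orthogonal harmonic

  set.seed(74)
  amps <- replicate(40, fit_sinusoid(x + rnorm(N, 0, 0.3), 4)$amplitude)
  expect_lt(abs(mean(amps) - 0.6), 3 * 0.3 * sqrt(2 / N))
})

test_that("dominant period excludes the full-genome harmonic when asked", {
  a <- 0:4631
  k16 <- cos(2 * pi * a / 4632) + 0.05 * cos(2 * pi * 6 * a / 4632)
  with_k1 <- dominant_period(k16, exclude_k1 = FALSE)
  expect_equal(with_k1$k, 1L)
  expect_equal(with_k1$wavelength, 4632)
  no_k1 <- dominant_period(k16, exclude_k1 = TRUE)
  expect_equal(no_k1$k, 6L)
  expect_equal(no_k1$wavelength, 772)
  # a k=1-only signal over noise: excluding k=1 leaves a weak residual peak
  set.seed(76)
  k1n <- 5 * cos(2 * pi * a / 4632) + rnorm(4632)
  strong <- dominant_period(k1n, exclude_k1 = FALSE)
  weak <- dominant_period(k1n, exclude_k1 = TRUE)
  expect_equal(strong$k, 1L)
  expect_gt(strong$g, 0.5)
  expect_lt(weak$g, 0.01)
  # ties resolve to the smaller harmonic
  tie <- cos(2 * pi * 3 * a / 4632) + cos(2 * pi * 5 * a / 4632)
  expect_equal(dominant_period(tie)$k, 3L)
  expect_error(dominant_period(rep(1, 100)), "flat spectrum")
})

test_that("signal-to-signal Pearson correlation behaves at the extremes", {
  set.seed(75)
  g <- rnorm(300)
  expect_equal(essential_density_correlation(g, -g)$r, -1, tolerance = 1e-12)
  ind <- essential_density_correlation(g, rnorm(300))
  expect_lt(abs(ind$r), 0.2)
  expect_error(essential_density_correlation(g, rnorm(100)), "length")
  expect_error(essential_density_correlation(g, rep(1, 300)), "constant")
})
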