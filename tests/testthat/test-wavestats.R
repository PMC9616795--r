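test_that("dip and excess mass handle degenerate samples", {
  expect_equal(dip_statistic(5), 0)
  expect_equal(dip_statistic(rep(2, 10)), 0)
  expect_warning(d <- excess_mass_statistic(rep(2, 10)), "degenerate")
  expect_equal(d, 0)
  expect_error(dip_statistic(numeric(0)), "empty")
})

test_that("the two-point sample matches its hand-derived values", {
  # brute force over unimodal CDFs pins dip({0,1}) at 1/4: the bands force
  # G(0) in [1/2 - t, t], so t >= 1/4, attained by the linear ramp
  expect_equal(dip_statistic(c(0, 1)), 0.25, tolerance = 1e-12)
  # excess mass: E2 - E1 = min(lambda, 1/2), maximal at the pair slope
  expect_equal(suppressWarnings(excess_mass_statistic(c(0, 1))), 0.5,
               tolerance = 1e-12)
})

test_that("excess mass equals twice the dip against the LP brute force", {
  set.seed(77)
  samples <- lapply(1:60, function(i) {
    n <- sample(2:8, 1)
    if (i %% 3 == 0) round(runif(n), 1) else rnorm(n)  # some with ties
  })
  oracle <- dip_lp_oracle(samples)
  for (i in seq_along(samples)) {
    expect_equal(dip_statistic(samples[[i]]), oracle[i], tolerance = 1e-9)
    expect_equal(
      suppressWarnings(excess_mass_statistic(samples[[i]], 1)),
      2 * oracle[i], tolerance = 1e-9)
  }
})

test_that("excess mass is invariant under affine transforms", {
  set.seed(13)
  x <- c(rnorm(30), rnorm(25, 4))
  d0 <- excess_mass_statistic(x)
  for (ab in list(c(3, -2), c(0.01, 100), c(-5, 0))) {
    expect_equal(excess_mass_statistic(ab[1] * x + ab[2]), d0,
                 tolerance = 1e-10)
  }
})

test_that("dip shrinks with sample size on uniform data", {
  set.seed(19)
  dips <- vapply(c(50, 200, 1000), function(n) dip_statistic(runif(n)),
                 numeric(1))
  expect_true(all(diff(dips) < 0))
  expect_lt(dips[3], 0.02)
})

test_that("separation monotonically increases the excess-mass statistic", {
  set.seed(23)
  med <- vapply(c(0, 3, 4.5, 6), function(sep) {
    median(vapply(1:40, function(s) {
      set.seed(1000 + s)
      excess_mass_statistic(c(rnorm(60), rnorm(60, sep)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("the bootstrap test rejects a separated mixture and recovers modes", {
  set.seed(3)
  x <- c(rnorm(48), rnorm(47, 6))
  r <- test_multimodality(x, B = 100, seed = 42)
  expect_s3_class(r, "mode_test")
  expect_equal(r$decision, "multimodal")
  expect_lte(r$p_value, 0.05)
  expect_equal(length(r$modes), 2)
  expect_equal(length(r$antimodes), length(r$modes) - 1)
  expect_lt(abs(r$modes[1] - 0), 0.7)
  expect_lt(abs(r$modes[2] - 6), 0.7)
  expect_lt(abs(r$antimodes[1] - 3), 1.5)
  expect_output(print(r), "multimodal")
  j <- jsonlite::fromJSON(mode_test_json(r))
  expect_equal(j$p_value, r$p_value)
  expect_error(test_multimodality(rnorm(5), seed = 1), "insufficient")
  expect_error(test_multimodality(rnorm(50)), "seed")
})

test_that("temporal windows partition the canonical axis", {
  expect_equal(assign_window(canonical_age(10, "pcw")), "early_fetal")
  expect_equal(assign_window(canonical_age(6, "postnatal_months")), "infant")
  expect_equal(assign_window(canonical_age(40, "postnatal_years")), "adult")
  expect_equal(assign_window(canonical_age(10, "postnatal_years")),
               "unclassified")
  w <- temporal_windows()
  expect_true(all(w$end_days[-nrow(w)] == w$start_days[-1]))
  ages <- c(canonical_age(seq(3.5, 37.5, 0.5), "pcw"),
            canonical_age(c(0.1, 0.9, 1.5, 2.5, 17, 19, 74), "postnatal_years"))
  lab <- assign_window(ages)
  expect_true(all(lab %in% c(w$window, "pre_embryonic")))
  # boundary ages land in the deeper (later) window: half-open rule
  expect_equal(assign_window(canonical_age(9, "pcw")), "early_fetal")
  expect_equal(assign_window(canonical_age(16, "pcw")), "mid_late_fetal")
})

test_that("window comparisons control the null and flag a shifted window", {
  ages <- rep(canonical_age(c(5, 12, 20, 30), "pcw"), each = 10)
  rej <- 0
  for (s in 1:150) {
    set.seed(s)
    coh <- data.frame(canonical_age_days = ages,
                      density_per_mm2 = rnorm(40, 100, 10))
    r <- compare_windows(coh, "density")
    rej <- rej + (r$omnibus$p <= 0.05)
  }
  expect_gt(rej / 150, 0.005)
  expect_lt(rej / 150, 0.12)
  # one window shifted by 3 pooled SDs is flagged pairwise
  hits <- 0
  for (s in 1:60) {
    set.seed(s)
    v <- rnorm(40, 100, 10)
    v[ages == ages[11]] <- v[ages == ages[11]] + 30
    coh <- data.frame(canonical_age_days = ages, density_per_mm2 = v)
    r <- compare_windows(coh, "density")
    pw <- r$pairwise
    sel <- pw$group1 == "early_fetal" | pw$group2 == "early_fetal"
    hits <- hits + all(pw$p_adjusted[sel] <= 0.05)
  }
  expect_gte(hits / 60, 0.95)
  # two single-value windows are insufficient
  expect_error(compare_windows(
    data.frame(canonical_age_days = canonical_age(c(5, 20), "pcw"),
               density_per_mm2 = c(1, 2)), "density"), "at least 2")
})

test_that("the BKY adjustment is anticonservative relative to plain BH", {
  set.seed(2)
  p <- c(runif(15, 0, 0.01), runif(35))
  bky <- p_adjust_bky(p)
  bh <- p.adjust(p, "BH")
  expect_true(all(bky <= bh + 1e-12))
  expect_true(all(bky >= 0 & bky <= 1))
  expect_equal(p_adjust_bky(numeric(0)), numeric(0))
})

test_that("nonparametric front end reproduces the standard identities", {
  x <- c(1.2, 3.1, 0.7, 2.2, 4.5)
  r <- nonparametric_test(x, x, "ks_2samp")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r2 <- nonparametric_test(1:10, (1:10)^3, "spearman")
  expect_equal(r2$statistic, 1)
  r3 <- nonparametric_test(1:10, 100:110, "mann_whitney")
  expect_lt(r3$p, 0.001)
  # exact enumeration: all 10 x 11 arrangements disjoint -> p = 2/C(21,10)
  expect_equal(r3$p, 2 / choose(21, 10), tolerance = 1e-12)
  expect_error(nonparametric_test(1:4, 1:5, "wilcoxon_paired"), "equal-length")
  m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5, 1, 3, 2), nrow = 4, byrow = TRUE)
  r4 <- nonparametric_test(m, method = "friedman")
  expect_true(r4$p >= 0 && r4$p <= 1)
})

test_that("trend fitting reproduces lines and localizes planted waves", {
  t <- seq(30, 200, length.out = 30)
  coh <- data.frame(canonical_age_days = t, density_per_mm2 = 2 + 0.5 * t)
  tf <- fit_trend(coh, "density")
  expect_lt(max(abs(tf$residuals)) / max(abs(coh$density_per_mm2)), 1e-6)
  expect_equal(length(tf$peaks), 0)
  # planted two-wave cohort: density peaks recovered within a week
  g <- generate_cohort(wave_spec(), seed = 4)
  pre <- g$cohort[g$cohort$canonical_age_days <= 210, ]
  tf2 <- fit_trend(pre, "density")
  for (pk in g$truth$density_peak_days)
    expect_lt(min(abs(tf2$peaks - pk)), 7)
  # refitting the fitted curve moves it very little (smoothing bias only)
  refit_in <- data.frame(canonical_age_days = tf2$x,
                         density_per_mm2 = tf2$fitted_points)
  tf3 <- fit_trend(refit_in, "density")
  expect_lt(max(abs(tf3$fitted_points - tf2$fitted_points)) /
            diff(range(tf2$fitted_points)), 0.12)
  for (pk in g$truth$density_peak_days) {  # the wave peaks survive a
    p2 <- tf2$peaks[which.min(abs(tf2$peaks - pk))]   # second smoothing pass
    expect_lt(min(abs(tf3$peaks - p2)), 4)
  }
  expect_error(fit_trend(coh[1:5, ], "density", knots = 6), "insufficient")
  expect_warning(fit_trend(coh, "density", knots = 5), "recommended")
  expect_error(predict(tf2, 1e6), "extrapolation")
  expect_equal(residuals(tf2), tf2$y - tf2$fitted_points)
})
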