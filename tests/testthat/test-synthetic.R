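test_that("column generator matches its Poisson intensity", {
  spec <- column_spec(layers = c(CP = 500), lambda_per_mm2 = 200,
                      column_width_um = 450)
  # expected count: 200 * 0.5 mm * 0.45 mm = 45
  counts <- vapply(1:300, function(s)
    nrow(generate_column(spec, seed = s)$cells), numeric(1))
  expect_equal(mean(counts), 45, tolerance = 3 * sqrt(45 / 300) / 45)
  expect_gt(var(counts), 45 * 0.7)   # Poisson: variance tracks the mean
  expect_lt(var(counts), 45 * 1.4)
})

test_that("column generator is deterministic and passes validation", {
  spec <- column_spec()
  a <- generate_column(spec, seed = 42)
  b <- generate_column(spec, seed = 42)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  expect_silent(microdyn:::validate_cells(a$cells))
  expect_error(column_spec(layers = c(MZ = 0, CP = 100)), "zero-thickness")
})

test_that("a column with no migratory cells has no low-circularity shapes", {
  spec <- column_spec(migratory_fraction = 0)
  col <- generate_column(spec, seed = 3)
  circ <- circularity(col$cells$area_um2, col$cells$perimeter_um)
  expect_true(all(circ >= 0.3))
})

test_that("planted marker fractions are recovered in the long run", {
  spec <- column_spec(layers = c(CP = 2000), lambda_per_mm2 = 500,
                      ki67_fraction = 0.15)
  hits <- 0; tot <- 0
  for (s in 1:40) {
    cells <- generate_column(spec, seed = s)$cells
    hits <- hits + sum(cells$ki67); tot <- tot + nrow(cells)
  }
  expect_equal(hits / tot, 0.15, tolerance = 3 * sqrt(0.15 * 0.85 / tot) / 0.15)
})

test_that("noise-free cohorts reproduce the latent curves exactly", {
  spec <- wave_spec(density_lognorm_sd = 0, index_overdispersion = 0)
  grid <- seq(28, 196, by = 7)
  g <- generate_cohort(spec, n_cases = length(grid), age_grid = grid, seed = 1)
  expect_equal(g$cohort$density_per_mm2, spec$curves$D(grid))
  expect_equal(g$cohort$proliferative_index_pct, spec$curves$P(grid))
  expect_equal(g$cohort$apoptotic_index_pct, spec$curves$A(grid))
})

test_that("cohort generation is deterministic and in range", {
  spec <- wave_spec()
  a <- generate_cohort(spec, seed = 9)
  b <- generate_cohort(spec, seed = 9)
  expect_identical(a$cohort, b$cohort)
  expect_true(all(a$cohort$density_per_mm2 >= 0))
  expect_true(all(a$cohort$proliferative_index_pct >= 0 &
                  a$cohort$proliferative_index_pct <= 100))
  expect_true(all(a$cohort$apoptotic_index_pct >= 0 &
                  a$cohort$apoptotic_index_pct <= 100))
  expect_error(generate_cohort(spec, age_grid = c(-7, 14)), "support")
})

test_that("planted two-wave density values are bimodal by the excess-mass oracle", {
  spec <- wave_spec()
  g <- generate_cohort(spec, seed = 2)
  delta <- excess_mass_statistic(g$cohort$density_per_mm2, k = 1)
  # two strongly separated regimes give a much larger statistic than the
  # n-driven floor observed for unimodal samples of this size (~0.05)
  expect_gt(delta, 0.08)
})

test_that("flat trajectories are accepted as unimodal in most replicates", {
  spec <- wave_spec(prolif_amplitude = 0, density_amplitude = 0)
  ok <- 0
  for (s in 1:50) {
    g <- generate_cohort(spec, n_cases = 60, age_grid = seq(28, 196, 7),
                         seed = s)
    r <- test_multimodality(g$cohort$density_per_mm2, B = 60, seed = 1e4 + s)
    ok <- ok + (r$decision == "unimodal_not_rejected")
  }
  expect_gte(ok / 50, 0.9)
})

test_that("expression generator plants recoverable classes deterministically", {
  spec <- expr_spec(n_on = 40, n_off = 20, n_other = 10, de_n_up = 0,
                    de_n_down = 0)
  a <- generate_expression(spec, seed = 5)
  b <- generate_expression(spec, seed = 5)
  expect_identical(a$expr$tpm, b$expr$tpm)
  on_rows <- a$expr$tpm[names(which(a$classes == "On")), ]
  expect_true(all(on_rows > 2))
  off_rows <- a$expr$tpm[names(which(a$classes == "Off")), ]
  expect_true(all(off_rows == 0))
  # Other genes: expressed at some but not all timepoints
  tp <- a$expr$samples$timepoint_pcw
  for (gn in names(which(a$classes == "Other"))) {
    per_tp <- tapply(a$expr$tpm[gn, ] > 2, tp, all)
    expect_true(any(per_tp) && !all(per_tp))
  }
  expect_error(generate_expression(expr_spec(samples_per_timepoint = 0)))
})

test_that("an all-Off spec yields a zero matrix", {
  spec <- expr_spec(n_on = 0, n_off = 15, n_other = 0, de_n_up = 0,
                    de_n_down = 0)
  g <- generate_expression(spec, seed = 1)
  expect_true(all(g$expr$tpm == 0))
})
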