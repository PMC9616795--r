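make_expr <- function(values, tps = c(9, 12), per_tp = 5) {
  ns <- length(tps) * per_tp
  m <- matrix(rep(values, each = ns), nrow = length(values), byrow = TRUE,
              dimnames = list(paste0("g", seq_along(values)),
                              paste0("s", seq_len(ns))))
  meta <- data.frame(sample_id = colnames(m),
                     timepoint_pcw = rep(tps, each = per_tp))
  expression_matrix(m, meta)
}

test_that("constitutive classification applies the strict TPM rule", {
  e <- make_expr(c(5, 0, 2))
  cl <- classify_gene_expression(e)
  expect_equal(cl$class, c("On", "Off", "Off"))
  # TPM exactly 2.0 is not "> 2", so the gene cannot be On; with all
  # samples at the threshold the pass fraction is 0 -> Off by complement
  expect_false(cl$class[3] == "On")
  expect_true(all(sort(unique(cl$class)) %in% c("Off", "On", "Other")))
})

test_that("classification partitions the universe and ignores column order", {
  g <- generate_expression(expr_spec(n_on = 30, n_off = 20, n_other = 15),
                           seed = 7)
  cl <- classify_gene_expression(g$expr)
  expect_equal(nrow(cl), 65)
  expect_equal(sum(table(cl$class)), 65L)
  expect_equal(unname(cl$class), unname(g$classes[cl$gene_id]))
  # permute samples: identical classes
  perm <- sample(ncol(g$expr$tpm))
  e2 <- expression_matrix(g$expr$tpm[, perm], g$expr$samples[perm, ])
  cl2 <- classify_gene_expression(e2)
  expect_equal(cl2$class, cl$class)
  # restricting to a signature reports unmatched symbols
  cl3 <- classify_gene_expression(g$expr,
                                  genes = c(cl$gene_id[1:5], "NOSUCHGENE"))
  expect_equal(attr(cl3, "missing_genes"), "NOSUCHGENE")
  expect_equal(nrow(cl3), 5)
})

test_that("few-sample timepoints trigger a coarseness warning", {
  expect_warning(classify_gene_expression(make_expr(c(5, 0), per_tp = 3)),
                 "fewer than 5")
})

test_that("DE summaries reproduce the signature arithmetic", {
  # 27 up + 54 down among 906 tested signature genes: 81 DE, 8.94%
  genes <- sprintf("G%04d", 1:906)
  de <- data.frame(gene_id = genes,
                   transition = "9->12",
                   direction = rep(c("up", "down", "up"), c(27, 54, 825)),
                   significant = rep(c(TRUE, FALSE), c(81, 825)))
  s <- de_summary(de, genes)
  expect_equal(s$n_up, 27)
  expect_equal(s$n_down, 54)
  expect_equal(s$n_de, 81)
  expect_equal(s$percent_de, 100 * 81 / 906)
  expect_equal(round(s$percent_de, 2), 8.94)
  # empty table
  s0 <- de_summary(de[de$significant == FALSE, ][0, ], genes)
  expect_equal(nrow(s0), 0)
  # a gene up and down in one transition is a validation error
  bad <- rbind(de[1, ], transform(de[1, ], direction = "down"))
  expect_error(de_summary(bad, genes), "both up and down")
})

test_that("the rank-sum stand-in recovers a planted DE spike", {
  g <- generate_expression(expr_spec(), seed = 31)
  de <- de_ranksum(g$expr)
  expect_equal(attr(de, "method"), "ranksum_bh_synthetic_standin")
  sig <- de[de$transition == "12->16" & de$significant, ]
  sens <- mean(c(g$de_truth$up %in% sig$gene_id[sig$direction == "up"],
                 g$de_truth$down %in% sig$gene_id[sig$direction == "down"]))
  expect_gte(sens, 0.9)
  s <- de_summary(de, names(g$classes))
  expect_true(all(s$n_de <= s$n_tested))
})

test_that("TPM columns are properly normalised", {
  expect_equal(as.vector(tpm_from_counts(matrix(7), 1)), 1e6)
  m <- tpm_from_counts(matrix(c(10, 10), ncol = 1), c(1, 1))
  expect_equal(as.vector(m), c(5e5, 5e5))
  m2 <- tpm_from_counts(matrix(c(10, 10), ncol = 1), c(1, 2))
  expect_equal(m2[1] / m2[2], 2)
  expect_equal(sum(m2), 1e6)
  set.seed(4)
  counts <- matrix(rpois(60, 40), nrow = 10,
                   dimnames = list(NULL, paste0("s", 1:6)))
  tm <- tpm_from_counts(counts, runif(10, 0.5, 5))
  expect_equal(unname(colSums(tm)), rep(1e6, 6), tolerance = 1e-9)
  expect_warning(tpm_from_counts(cbind(counts, s7 = 0), runif(10, 0.5, 5)),
                 "zero counts")
  expect_error(tpm_from_counts(counts, c(-1, runif(9))))
})

test_that("MAD filtering removes exactly the planted outliers", {
  qc <- generate_qc_metrics(n_cells = 400, seed = 13)
  out <- mad_outlier_filter(qc$metrics)
  expect_identical(!out$keep, qc$truth_outlier)
  # a value at median + 4 MAD is removed, constant metrics remove nobody
  d <- data.frame(cell_id = sprintf("c%02d", 1:21),
                  a = c(seq(-1, 1, 0.1), numeric(0)), b = 1)
  med <- median(d$a); madu <- median(abs(d$a - med))
  d$a[21] <- med + 4 * madu
  out2 <- mad_outlier_filter(d)
  expect_identical(which(!out2$keep), 21L)
  expect_error(mad_outlier_filter(d[1:2, ]), "at least 3")
})

test_that("the MAD keep-set shrinks as k decreases", {
  qc <- generate_qc_metrics(n_cells = 300, outlier_fraction = 0, seed = 8)
  m <- qc$metrics
  m$nCount <- rnorm(300, 5000, 500)       # heavier tail than uniform
  kept <- vapply(c(4, 3, 2, 1), function(k)
    sum(mad_outlier_filter(m, k = k)$keep), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("cycling fractions respect the minimum-cell rule and peak shape", {
  ann <- data.frame(age_pcw = rep(c(9, 10), c(100, 49)),
                    cycling = c(rep(c(1, 0), c(10, 90)), rep(0, 49)))
  cf <- cycling_fraction_by_age(ann)
  expect_equal(cf$age_pcw, 9)
  expect_equal(cf$fraction, 0.10)
  expect_error(cycling_fraction_by_age(ann[0, ]), "empty")
  # planted bimodal profile: local maxima at the planted peak ages
  cells_per_age <- rep(800, 18); cells_per_age[9] <- 49   # age 15 pcw
  g <- generate_cycling_annotations(cells_per_age = cells_per_age, seed = 3)
  cf2 <- cycling_fraction_by_age(g$annotations)
  expect_false(15 %in% cf2$age_pcw)   # the 49-cell age is excluded
  early <- cf2[cf2$age_pcw <= 13, ]
  late <- cf2[cf2$age_pcw > 13, ]
  expect_lte(abs(early$age_pcw[which.max(early$fraction)] - 9), 1)
  expect_lte(abs(late$age_pcw[which.max(late$fraction)] - 18), 1)
})
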