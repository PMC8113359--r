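test_that("cohort generation honours counts, schema and determinism", {
  cfg <- cohort_config(n_genes = 100, seed = 4)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$genes), 100)
  expect_equal(nrow(co$truth), 100)
  expect_equal(nrow(co$expression$values), 100)
  expect_silent(validate_gene_table(co$genes))
  # truth rows retrievable by gene id
  expect_identical(co$truth$gene_id, co$genes$gene_id)
  # identical config, identical output
  co2 <- generate_cohort(cohort_config(n_genes = 100, seed = 4))
  expect_identical(co, co2)
  # different seed, different draws
  co3 <- generate_cohort(cohort_config(n_genes = 100, seed = 5))
  expect_false(identical(co$genes$poly_n, co3$genes$poly_n))
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_genes = 0), "n_genes")
  expect_error(cohort_config(theta_s = -1), "theta_s")
  expect_error(cohort_config(m = 1), "'m'")
  expect_error(cohort_config(ages = 3), "ages")
  expect_error(cohort_config(sites_s = 0), "sites_s")
})

test_that("the planted selection map is an exact monotone transform of REA", {
  cfg <- cohort_config(n_genes = 2000, a1 = -0.5, c1 = 0, seed = 6)
  co <- generate_cohort(cfg)
  expect_equal(cor(co$truth$truth_ne_s, co$truth$truth_rea,
                   method = "spearman"), -1)
  expect_true(all(co$truth$truth_ne_s > 0))
  expect_true(all(co$truth$truth_alpha_m >= 0 & co$truth$truth_alpha_m <= 1))
})

test_that("with selection switched off the count ratios are neutral", {
  # a0 -> -Inf plants Ne*s ~ 0 for every gene; the mean observed ratios of
  # nonsynonymous to synonymous counts then equal the mutation-rate ratio
  cfg <- cohort_config(n_genes = 3000, a0 = -30, theta_s = 5, seed = 8)
  co <- generate_cohort(cfg)
  mu <- cfg$mu_ratio
  ratio_poly <- mean(co$genes$poly_n) / mean(co$genes$poly_s)
  se_poly <- ratio_poly * sqrt(1 / sum(co$genes$poly_n) + 1 / sum(co$genes$poly_s))
  expect_lt(abs(ratio_poly - mu), 3 * se_poly)
  ratio_div <- mean(co$genes$div_n) / mean(co$genes$div_s)
  se_div <- ratio_div * sqrt(1 / sum(co$genes$div_n) + 1 / sum(co$genes$div_s))
  expect_lt(abs(ratio_div - mu), 3 * se_div)
})

test_that("gene age reflects the planted lifespan gradient", {
  # late-expressed genes (high REA) are under weaker purifying selection and
  # are therefore younger on average
  cfg <- cohort_config(n_genes = 4000, seed = 9)
  co <- generate_cohort(cfg)
  expect_lt(cor(co$truth$truth_t_bar, co$truth$truth_rea,
                method = "spearman"), 0)
  expect_lt(cor(co$genes$gene_age, co$truth$truth_rea,
                method = "spearman"), 0)
})

test_that("cohorts round-trip through the TSV writers", {
  cfg <- cohort_config(n_genes = 20, seed = 10)
  co <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  x <- read_expression_matrix(file.path(d, "expression.tsv"),
                              file.path(d, "samples.tsv"))
  expect_equal(x$values, co$expression$values, tolerance = 1e-12)
  g <- read_gene_table(file.path(d, "genes.tsv"))
  expect_equal(g$poly_n, co$genes$poly_n)
  tr <- read.delim(file.path(d, "truth.tsv"))
  expect_true(all(startsWith(setdiff(names(tr), "gene_id"), "truth_")))
})

test_that("paralog pairs are disjoint, seeded, and carry the planted sign", {
  cfg <- cohort_config(n_genes = 200, seed = 12)
  pairs <- generate_paralog_pairs(cfg, 10)
  expect_equal(nrow(pairs), 10)
  expect_true(all(pairs$gene_a != pairs$gene_b))
  expect_true(all(pairs$gene_a < pairs$gene_b))
  expect_false(any(duplicated(c(pairs$gene_a, pairs$gene_b))))
  expect_identical(pairs, generate_paralog_pairs(cfg, 10))
  expect_error(generate_paralog_pairs(cfg, 101), "exceeds")
  # with a1 < 0, orienting each pair by increasing REA makes the age
  # difference negative on average
  big <- generate_paralog_pairs(cohort_config(n_genes = 4000, seed = 13), 2000)
  d_age <- big$gene_age_b - big$gene_age_a
  d_rea <- big$rea_b - big$rea_a
  expect_lt(mean(d_age * sign(d_rea)), 0)
})
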