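test_that("REA is the OLS slope of log expression on age", {
  expect_equal(compute_rea(make_expr(c(0.5, 1.0, 1.5), 1:3), "g01"), 0.5)
  expect_equal(compute_rea(make_expr(c(2, 2, 2), 1:3), "g01"), 0)
  # hand OLS: cov/var = -1/5
  expect_equal(compute_rea(make_expr(c(2, 1, 2, 1), 1:4), "g01"), -0.2)
  expect_error(compute_rea(make_expr(c(1, 2), c(3, 3)), "g01"), "distinct ages")
  expect_error(compute_rea(make_expr(1:3, 1:3), "nope"), "not found")
})

test_that("REA is invariant to level shifts and scales inversely with age units", {
  x <- make_expr(c(1.2, 0.7, 2.1, 1.9, 2.5), 1:5)
  base <- compute_rea(x, "g01")
  shifted <- make_expr(c(1.2, 0.7, 2.1, 1.9, 2.5) + 10, 1:5)
  expect_equal(compute_rea(shifted, "g01"), base)
  rescaled <- make_expr(c(1.2, 0.7, 2.1, 1.9, 2.5), (1:5) * 7)
  expect_equal(compute_rea(rescaled, "g01"), base / 7)
})

test_that("vectorised slopes agree with the per-gene computation", {
  set.seed(42)
  vals <- matrix(rnorm(50), nrow = 5)
  x <- make_expr(vals, rep(1:5, each = 2))
  sl <- rea_slopes(x)
  for (g in rownames(x$values)) expect_equal(sl[[g]], compute_rea(x, g))
})

test_that("age of maximal expression uses age-group means, ties to youngest", {
  expect_equal(age_of_max_expression(make_expr(c(1, 2, 3), 1:3), "g01"), 3)
  expect_equal(age_of_max_expression(make_expr(c(1, 1, 1), 1:3), "g01"), 1)
  expect_equal(age_of_max_expression(make_expr(c(1, 5, 2), 1:3), "g01"), 2)
  # replicate structure: means decide, not single samples
  x <- make_expr(c(0, 4, 3, 3), c(1, 1, 2, 2))
  expect_equal(age_of_max_expression(x, "g01"), 2)
})

test_that("tau spans [0, 1] with the documented endpoints and is scale-free", {
  expect_equal(compute_tau(rep(3, 5)), 0)
  expect_equal(compute_tau(c(2, 0, 0, 0, 0)), 1)
  expect_equal(compute_tau(c(1, 0.5)), 0.5)
  v <- c(4, 1, 0.2, 2)
  expect_equal(compute_tau(v * 100), compute_tau(v))
  expect_error(compute_tau(c(0, 0, 0)), "zero")
  expect_error(compute_tau(5), "2 tissues")
})

test_that("observed pN/pS follows the site-fraction definition", {
  expect_equal(compute_pnps(10, 10, 100, 50), 0.5)
  expect_equal(compute_pnps(0, 5, 100, 50), 0)
  # undefined, not infinite, without synonymous polymorphism
  expect_true(is.na(compute_pnps(3, 0, 100, 50)))
  # equal per-site fractions give 1 regardless of site totals
  expect_equal(compute_pnps(30, 9, 300, 90), 1)
  expect_error(compute_pnps(-1, 5, 100, 50), "non-negative")
})

test_that("percentile classes are deterministic inverse-ECDF cuts", {
  cls <- classify_age_groups(1:100)
  expect_identical(which(cls$labels == "early"), 1:10)
  expect_identical(which(cls$labels == "late"), 91:100)
  # ten distinct genes: exactly one in each extreme class
  cls10 <- classify_age_groups(c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6))
  expect_equal(sum(cls10$labels == "early"), 1)
  expect_equal(sum(cls10$labels == "late"), 1)
  expect_equal(cls10$labels[which.min(c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6))],
               factor("early", levels = c("early", "middle", "late")))
  expect_error(classify_age_groups(1:100, 50, 50), "strictly less")
  expect_error(classify_age_groups(rep(1, 20)), "equal")
  expect_error(classify_age_groups(1:5), "at least 10")
})

test_that("early/late dN/dS contrast follows its definition and bounds", {
  labels <- classify_age_groups(1:20)
  dn <- numeric(20)
  dn[labels$labels == "early"] <- 0.1
  dn[labels$labels == "late"] <- 0.3
  expect_equal(delta_r_ns(dn, labels), 1.0)
  # equal class means give 0
  dn[labels$labels == "late"] <- 0.1
  expect_equal(delta_r_ns(dn, labels), 0)
  # one extinct class mean hits the range endpoint -2
  dn[labels$labels == "early"] <- 0.2
  dn[labels$labels == "late"] <- 0
  expect_equal(delta_r_ns(dn, labels), -2)
  # antisymmetry under swapping the class labels
  set.seed(1)
  dn <- runif(20)
  swapped <- labels
  lv <- as.character(labels$labels)
  swapped$labels <- factor(ifelse(lv == "early", "late",
                                  ifelse(lv == "late", "early", "middle")),
                           levels = c("early", "middle", "late"))
  expect_equal(delta_r_ns(dn, swapped), -delta_r_ns(dn, labels))
})

test_that("the metrics pipeline appends the per-gene columns", {
  cfg <- cohort_config(n_genes = 50, seed = 2)
  co <- generate_cohort(cfg)
  g <- compute_gene_metrics(co$expression, co$genes)
  expect_true(all(c("rea", "mean_expr", "tau", "pn_ps", "age_class")
                  %in% names(g)))
  expect_true(all(g$tau >= 0 & g$tau <= 1))
  expect_true(all(g$age_class %in% c("early", "middle", "late")))
  # estimated REA tracks the planted slopes closely
  expect_gt(cor(g$rea, co$truth$truth_rea), 0.95)
})
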