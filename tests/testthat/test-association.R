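test_that("Spearman test matches hand-ranked values and is monotone-invariant", {
  expect_equal(spearman_test(1:10, 1:10)$rho, 1)
  expect_equal(spearman_test(1:10, 10:1)$rho, -1)
  # hand computation: d = (0,0,0,1,-1), rho = 1 - 6*2/(5*24) = 0.9
  expect_equal(spearman_test(1:5, c(1, 2, 3, 5, 4))$rho, 0.9)
  set.seed(21)
  x <- rnorm(40); y <- x + rnorm(40)
  base <- spearman_test(x, y)
  warped <- spearman_test(exp(x), y^3 + 5 * y)
  expect_equal(warped$rho, base$rho)
  expect_equal(warped$p, base$p)
  expect_error(spearman_test(rep(1, 10), 1:10), "constant")
  expect_error(spearman_test(1:3, 3:1), "5 complete")
})

test_that("REA regression reproduces planted coefficients exactly", {
  set.seed(22)
  tab <- data.frame(rea = rnorm(50), mean_expr = rnorm(50))
  tab$y <- 1 + 2 * tab$rea + 3 * tab$mean_expr
  fit <- fit_rea_regression(tab, "y")
  expect_equal(unname(fit$coefficients), c(1, 2, 3), tolerance = 1e-10)
  expect_equal(fit$b1, 2, tolerance = 1e-10)
  expect_equal(fit$n_used, 50)
  # tissue enters as fixed per-tissue intercepts and is removed exactly
  tab$tissue <- rep(c("a", "b"), 25)
  tab$y2 <- tab$y + ifelse(tab$tissue == "b", 7, 0)
  fit2 <- fit_rea_regression(tab, "y2")
  expect_equal(unname(fit2$coefficients[["rea"]]), 2, tolerance = 1e-10)
  # collinear covariates are reported by name
  tab$dup <- tab$rea
  expect_error(fit_rea_regression(tab, "y", covariates = c("mean_expr", "dup")),
               "dup")
})

test_that("REA regression drops incomplete rows and needs 10 of them", {
  set.seed(23)
  tab <- data.frame(rea = rnorm(30), mean_expr = rnorm(30))
  tab$y <- tab$rea + rnorm(30)
  tab$y[1:5] <- NA
  fit <- fit_rea_regression(tab, "y")
  expect_equal(fit$n_used, 25)
  expect_error(fit_rea_regression(tab[1:12, ], "y"), "fewer than 10")
})

test_that("null responses give calibrated Spearman rejection rates", {
  set.seed(24)
  rea <- rnorm(80)
  mean_expr <- rnorm(80)
  pv <- replicate(400, {
    tab <- data.frame(rea = rea, mean_expr = mean_expr, y = rnorm(80))
    fit_rea_regression(tab, "y")$p_value
  })
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("paralog contrasts recover exact slopes and ignore orientation", {
  set.seed(25)
  n <- 30
  rea_a <- rnorm(n); rea_b <- rnorm(n)
  pairs <- data.frame(gene_a = sprintf("a%02d", 1:n),
                      gene_b = sprintf("b%02d", 1:n),
                      rea_a = rea_a, rea_b = rea_b,
                      stat_a = 0, stat_b = 2 * (rea_b - rea_a))
  fit <- paralog_contrasts(pairs, "stat")
  expect_equal(fit$b1, 2, tolerance = 1e-10)
  # flipping every pair leaves the slope unchanged
  flipped <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a,
                        rea_a = pairs$rea_b, rea_b = pairs$rea_a,
                        stat_a = pairs$stat_b, stat_b = pairs$stat_a)
  expect_equal(paralog_contrasts(flipped, "stat")$b1, fit$b1,
               tolerance = 1e-10)
  expect_error(paralog_contrasts(pairs[1:5, ], "stat"), "10")
  pairs$rea_b <- pairs$rea_a
  expect_error(paralog_contrasts(pairs, "stat"), "zero")
})

test_that("paralog contrasts from a planted cohort carry the age signal", {
  pairs <- generate_paralog_pairs(cohort_config(n_genes = 3000, seed = 26),
                                  1500)
  fit <- paralog_contrasts(pairs, "gene_age")
  expect_lt(fit$b1, 0)
  expect_lt(fit$spearman_rho, 0)
  expect_lt(fit$p_value, 0.01)
})

test_that("binary annotations separate perfectly or stay null as planted", {
  set.seed(27)
  tab <- data.frame(rea = rnorm(1000))
  tab$driver <- tab$rea > median(tab$rea)
  res <- binary_trait_association(tab, "driver")
  expect_lt(res$wilcoxon_p, 1e-10)
  expect_gt(res$spearman_rho, 0.5)
  # equal-count bins over n = 1000 with 10 bins are all of size 100
  expect_true(all(res$bins$n == 100))
  expect_true(all(diff(res$bins$mean_rea) > 0))
  # random annotation: uniform p-values over seeds
  pv <- sapply(1:300, function(s) {
    set.seed(1000 + s)
    tab$rand <- as.logical(rbinom(1000, 1, 0.2))
    binary_trait_association(tab, "rand")$spearman_p
  })
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  tab$all <- TRUE
  expect_error(binary_trait_association(tab, "all"), "single class")
})
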