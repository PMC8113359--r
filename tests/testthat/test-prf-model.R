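test_that("g_integral matches limits and a brute-force quadrature oracle", {
  # neutral limit: integrand reduces to x^(n-1)
  expect_equal(g_integral(0, 1), 1)
  expect_equal(g_integral(0, 3), 1 / 3)
  expect_equal(g_integral(1e-9, 5), 1 / 5, tolerance = 1e-9)
  # selected case against high-resolution trapezoid evaluation
  oracle <- trapezoid(function(x) {
    out <- (1 - exp(-2 * (1 - x))) / (2 * (1 - x))
    out
  }, ends = c((1 - exp(-2)) / 2, 1))
  expect_equal(g_integral(2, 1), oracle, tolerance = 1e-8)
  # series and quadrature branches agree at the same point near the threshold
  g <- 2e-6; n <- 4
  series <- 1 / n - g / (2 * n * (n + 1)) + g^2 / (3 * n * (n + 1) * (n + 2))
  expect_equal(g_integral(g, n), series, tolerance = 1e-10)
})

test_that("synonymous expectation equals Watterson's harmonic sum", {
  for (m in c(2, 5, 10, 30)) {
    p <- prf_params(0, 0.5, 1, m, theta_s = 1)
    expect_equal(expected_poly_sites(p)[["n_S"]],
                 sum(1 / seq_len(m - 1)), tolerance = 1e-12)
  }
  # spot value: H_9
  expect_equal(expected_poly_sites(prf_params(0, 0.5, 1, 10))[["n_S"]],
               2.828968, tolerance = 1e-6)
})

test_that("segregating-site expectations collapse to the neutral rates", {
  # n_B per unit beneficial mutation rate equals n_S per unit synonymous rate
  p <- prf_params(1e-9, 0.3, 2, 10, theta_s = 1)
  n <- expected_poly_sites(p)
  expect_equal(n[["n_B"]] / (0.3 * 2), n[["n_S"]], tolerance = 1e-8)
  for (mu in c(0.5, 1, 2.5)) {
    expect_equal(pn_ps_expected(prf_params(1e-9, 0.7, mu, 20)), mu,
                 tolerance = 1e-8)
  }
})

test_that("expected pN/pS matches an independent quadrature oracle", {
  p <- prf_params(2, 0.1, 1, 20)
  expect_equal(pn_ps_expected(p), oracle_pnps(2, 0.1, 1, 20),
               tolerance = 1e-8)
  p2 <- prf_params(5, 0.8, 2.5, 12)
  expect_equal(pn_ps_expected(p2), oracle_pnps(5, 0.8, 2.5, 12),
               tolerance = 1e-7)
})

test_that("mirror symmetry: swapping (alpha_m, s) for (1-alpha_m, -s) is invariant", {
  for (g in c(0.5, 2, 8)) {
    for (a in c(0, 0.2, 0.9)) {
      expect_equal(agesel:::.pn_ps_raw(g, a, 1.5, 15),
                   agesel:::.pn_ps_raw(-g, 1 - a, 1.5, 15),
                   tolerance = 1e-10)
      expect_equal(agesel:::.dn_ds_limit_raw(g, a, 1.5),
                   agesel:::.dn_ds_limit_raw(-g, 1 - a, 1.5),
                   tolerance = 1e-10)
    }
  }
})

test_that("fixed-site expectations follow the divergence model", {
  # synonymous: theta * (t_div + 1/m + 1)
  f <- expected_fixed_sites(prf_params(0, 0.5, 1, 2, t_div = 10))
  expect_equal(f[["F_S"]], 11.5)
  # neutral limit: nonsynonymous total reduces to mu_ratio * F_S
  f0 <- expected_fixed_sites(prf_params(1e-9, 0.3, 2, 10, t_div = 5))
  expect_equal(f0[["F_B"]] + f0[["F_D"]], 2 * f0[["F_S"]], tolerance = 1e-7)
  # no beneficial fixations without beneficial mutations
  fa <- expected_fixed_sites(prf_params(3, 0, 1, 10, t_div = 5))
  expect_identical(fa[["F_B"]], 0)
  expect_error(expected_fixed_sites(prf_params(1, 0.5, 1, 10)), "t_div")
})

test_that("long-divergence dN/dS has the closed-form endpoints", {
  expect_equal(dn_ds_limit(prf_params(1e-9, 0.5, 1, 10)), 1, tolerance = 1e-8)
  expect_equal(dn_ds_limit(prf_params(1, 0, 1, 10)), 1 / (exp(1) - 1),
               tolerance = 1e-12)
  expect_equal(dn_ds_limit(prf_params(1, 1, 1, 10)), 1 / (1 - exp(-1)),
               tolerance = 1e-12)
})

test_that("dN/dS is monotone in selection strength at the alpha_m extremes", {
  xs <- seq(0.2, 10, length.out = 25)
  pure_del <- vapply(xs, function(x) dn_ds_limit(prf_params(x, 0, 1, 10)),
                     numeric(1))
  pure_ben <- vapply(xs, function(x) dn_ds_limit(prf_params(x, 1, 1, 10)),
                     numeric(1))
  expect_true(all(diff(pure_del) < 0))
  expect_true(all(pure_del < 1))
  expect_true(all(diff(pure_ben) > 0))
  expect_true(all(pure_ben > 1))
})

test_that("ratios are independent of the absolute mutation scale", {
  for (th in 10^seq(-3, 3)) {
    p <- prf_params(2, 0.3, 1.5, 20, t_div = 8, theta_s = th)
    expect_equal(pn_ps_expected(p),
                 pn_ps_expected(prf_params(2, 0.3, 1.5, 20, theta_s = 1)),
                 tolerance = 1e-10)
    expect_equal(dn_ds_expected(p),
                 dn_ds_expected(prf_params(2, 0.3, 1.5, 20, t_div = 8)),
                 tolerance = 1e-10)
  }
})

test_that("finite-divergence dN/dS converges to the long-divergence limit", {
  lim <- dn_ds_limit(prf_params(2, 0.2, 1, 10))
  tds <- c(10, 100, 1000, 1e4)
  gaps <- vapply(tds, function(t) {
    abs(dn_ds_expected(prf_params(2, 0.2, 1, 10, t_div = t)) - lim)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)] / lim, 1e-3)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(prf_params(-1, 0.5, 1, 10), "ne_s")
  expect_error(prf_params(1, 1.5, 1, 10), "alpha_m")
  expect_error(prf_params(1, 0.5, 0, 10), "mu_ratio")
  expect_error(prf_params(1, 0.5, 1, 1), "m")
})
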