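#' Parameters of the Poisson random field selection model
#'
#' Bundles the parameters of the two-effect Poisson random field (PRF) model
#' of molecular evolution used throughout the package.  Nonsynonymous
#' mutations arise at a total rate `mu_ratio` times the synonymous rate; a
#' fraction `alpha_m` of them are beneficial with scaled selection strength
#' `+ne_s` (as homozygotes), the remaining fraction deleterious with `-ne_s`,
#' and heterozygotes are intermediate.  Synonymous mutations are neutral.
#' Sites evolve independently, so counts of segregating and fixed sites are
#' Poisson with the expectations computed by [expected_poly_sites()] and
#' [expected_fixed_sites()].
#'
#' @param ne_s Scaled selection magnitude (effective population size times
#'   the homozygous fitness effect), dimensionless, `>= 0`.
#' @param alpha_m Fraction of new nonsynonymous mutations that are
#'   beneficial, in `[0, 1]`.
#' @param mu_ratio Ratio of total nonsynonymous to synonymous mutation rates
#'   for the gene (estimated in practice as the ratio of nonsynonymous to
#'   synonymous site counts), `> 0`.
#' @param m Sample size in gene copies, integer `>= 2`.
#' @param t_div Divergence time between the two species, in units of
#'   `2 * Ne` generations; only required by the finite-divergence
#'   expectations ([expected_fixed_sites()], [dn_ds_expected()]).
#' @param theta_s Population mutation scale `4 * Ne * muS` for the gene's
#'   synonymous sites.  Sets the absolute scale of expected counts and
#'   cancels from all ratios.
#'
#' @return An object of class `prf_params` (a validated list).
#' @examples
#' p <- prf_params(ne_s = 2, alpha_m = 0.1, mu_ratio = 2.5, m = 20)
#' pn_ps_expected(p)
#' dn_ds_limit(p)
#' @export
prf_params <- function(ne_s, alpha_m, mu_ratio, m, t_div = NULL, theta_s = 1) {
  stopifnot(is.numeric(ne_s), length(ne_s) == 1L, is.finite(ne_s))
  if (ne_s < 0) stop("'ne_s' must be >= 0 (the sign is carried by the mutation class)")
  if (!is.numeric(alpha_m) || alpha_m < 0 || alpha_m > 1)
    stop("'alpha_m' must lie in [0, 1]")
  if (!is.numeric(mu_ratio) || mu_ratio <= 0) stop("'mu_ratio' must be > 0")
  if (!is.numeric(m) || m < 2 || m != round(m)) stop("'m' must be an integer >= 2")
  if (!is.null(t_div) && (!is.numeric(t_div) || t_div <= 0))
    stop("'t_div' must be > 0 when supplied")
  if (!is.numeric(theta_s) || theta_s <= 0) stop("'theta_s' must be > 0")
  structure(list(ne_s = ne_s, alpha_m = alpha_m, mu_ratio = mu_ratio,
                 m = as.integer(m), t_div = t_div, theta_s = theta_s),
            class = "prf_params")
}

#' @export
print.prf_params <- function(x, ...) {
  cat("PRF model parameters\n")
  cat(sprintf("  Ne*s     = %g\n  alpha_m  = %g\n  muN/muS  = %g\n  m        = %d\n",
              x$ne_s, x$alpha_m, x$mu_ratio, x$m))
  if (!is.null(x$t_div)) cat(sprintf("  t_div    = %g (units of 2Ne generations)\n", x$t_div))
  cat(sprintf("  theta_S  = %g\n", x$theta_s))
  invisible(x)
}

## (1 - exp(-u)) / u, the sojourn/fixation kernel, with a series branch so
## the removable singularity at u = 0 evaluates to 1 exactly.
.expm1_ratio <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-5
  out[small] <- 1 - u[small] / 2 + u[small]^2 / 6
  out[!small] <- -expm1(-u[!small]) / u[!small]
  out
}

## u / (1 - exp(-u)): relative fixation rate of a mutation with scaled
## effect u versus a neutral one.  Series branch near 0.
.fix_factor <- function(u) {
  if (abs(u) < 1e-6) return(1 + u / 2 + u^2 / 12)
  u / (-expm1(-u))
}

.harmonic <- function(n) if (n < 1) 0 else sum(1 / seq_len(n))

.NEUTRAL_EPS <- 1e-6   # |Ne*s| below which the series branch is used

#' Fixation-time integral of the PRF divergence model
#'
#' Evaluates `G(n) = integral over x in (0,1) of
#' x^(n-1) * (1 - exp(-g*(1-x))) / (g*(1-x)) dx`, where `g` is the signed
#' scaled selection coefficient.  `G` with `+g` applies to beneficial
#' mutations; replacing `g` by `-g` gives the deleterious counterpart.  At
#' `g = 0` the bracket is 1 and `G(n) = 1/n`; a second-order series branch
#' is used for `|g| < 1e-6`.
#'
#' @param ne_s Signed scaled selection coefficient.
#' @param n Positive integer (the sample size the integral is evaluated for).
#' @return The value of the integral (scalar).
#' @export
g_integral <- function(ne_s, n) {
  stopifnot(is.numeric(ne_s), length(ne_s) == 1L, is.finite(ne_s),
            is.numeric(n), n >= 1, n == round(n))
  if (abs(ne_s) < .NEUTRAL_EPS) {
    ## int x^(n-1) (1 - g(1-x)/2 + g^2 (1-x)^2/6) dx via beta integrals
    return(1 / n - ne_s / (2 * n * (n + 1)) + ne_s^2 / (3 * n * (n + 1) * (n + 2)))
  }
  f <- function(x) x^(n - 1) * .expm1_ratio(ne_s * (1 - x))
  q <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                        subdivisions = 500L)
  if (q$message != "OK")
    stop("g_integral: quadrature failed (", q$message, ") at ne_s = ", ne_s,
         ", n = ", n)
  q$value
}

## Integral for the expected number of segregating nonsynonymous sites of
## one selective class, per unit 4*Ne*mu of that class:
##   J(g, m) = int_0^1 [ (1 - exp(-4g(1-p))) / ((1 - exp(-4g)) p (1-p)) ]
##             * [ 1 - p^m - (1-p)^m ] dp
## Neutral limit J(0, m) = H_{m-1}; first-order series used for |g| small.
.poly_integral <- function(gamma, m) {
  if (abs(gamma) < .NEUTRAL_EPS) {
    return(.harmonic(m - 1) + 2 * gamma * (m - 1) / (m + 1))
  }
  u <- 4 * gamma
  ## sojourn-density factor (1 - e^{-u(1-p)}) / (1 - e^{-u}); for u < 0 the
  ## algebraically identical form (e^u - e^{up}) / (e^u - 1) avoids overflow
  ratio_fun <- if (u > 0) {
    function(p) -expm1(-u * (1 - p)) / (-expm1(-u))
  } else {
    function(p) (exp(u) - exp(u * p)) / expm1(u)
  }
  f <- function(p) {
    seg <- 1 - p^m - (1 - p)^m
    ## endpoints are removable: integrand -> m at p = 0, -> 0 at p = 1
    val <- ratio_fun(p) / (p * (1 - p)) * seg
    val[p == 0] <- m
    val[p == 1] <- 0
    val
  }
  q <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                        subdivisions = 500L)
  if (q$message != "OK")
    stop(".poly_integral: quadrature failed (", q$message, ") at gamma = ",
         gamma, ", m = ", m)
  q$value
}

#' Expected numbers of segregating sites under the PRF model
#'
#' Computes the expected numbers of polymorphic sites in a sample of `m`
#' gene copies at which beneficial nonsynonymous (`n_B`), deleterious
#' nonsynonymous (`n_D`) and neutral synonymous (`n_S`) mutations segregate.
#' The synonymous expectation has the closed form
#' `theta_s * sum_{k=1}^{m-1} 1/k` (Watterson's constant); the selected
#' classes require numerical quadrature over the diffusion sojourn density.
#'
#' @param params A [prf_params()] object.
#' @return Named numeric vector with components `n_B`, `n_D`, `n_S`.
#' @export
expected_poly_sites <- function(params) {
  stopifnot(inherits(params, "prf_params"))
  muN <- params$theta_s * params$mu_ratio
  c(n_B = muN * params$alpha_m * .poly_integral(params$ne_s, params$m),
    n_D = muN * (1 - params$alpha_m) * .poly_integral(-params$ne_s, params$m),
    n_S = params$theta_s * .harmonic(params$m - 1))
}

#' Expected pN/pS ratio under the PRF model
#'
#' The ratio of expected counts of segregating nonsynonymous to synonymous
#' sites, `(n_B + n_D) / n_S`.  Independent of the absolute mutation scale
#' `theta_s`; depends only on `ne_s`, `alpha_m`, `mu_ratio` and the sample
#' size `m`.
#'
#' @inheritParams expected_poly_sites
#' @return Expected pN/pS (scalar).
#' @export
pn_ps_expected <- function(params) {
  n <- expected_poly_sites(params)
  unname((n[["n_B"]] + n[["n_D"]]) / n[["n_S"]])
}

#' Expected numbers of fixed sites under the PRF model
#'
#' Expected numbers of sites fixed for beneficial (`F_B`) and deleterious
#' (`F_D`) nonsynonymous mutations and for synonymous mutations (`F_S`)
#' between two species that diverged `t_div` (units of `2 Ne` generations)
#' ago, when one species is sampled at `m` copies and the other at one.
#' `F_S = theta_s * (t_div + 1/m + 1)`; the selected classes scale the
#' divergence window by the relative fixation rate and the boundary terms
#' by the integrals computed in [g_integral()].
#'
#' @inheritParams expected_poly_sites
#' @return Named numeric vector with components `F_B`, `F_D`, `F_S`.
#' @export
expected_fixed_sites <- function(params) {
  stopifnot(inherits(params, "prf_params"))
  if (is.null(params$t_div))
    stop("expected_fixed_sites requires 't_div' in the parameter object")
  g <- params$ne_s
  m <- params$m
  muN <- params$theta_s * params$mu_ratio
  FB <- muN * params$alpha_m * .fix_factor(g) *
    (params$t_div + g_integral(g, m) + g_integral(g, 1))
  FD <- muN * (1 - params$alpha_m) * .fix_factor(-g) *
    (params$t_div + g_integral(-g, m) + g_integral(-g, 1))
  c(F_B = FB, F_D = FD,
    F_S = params$theta_s * (params$t_div + 1 / m + 1))
}

#' Expected dN/dS at finite divergence time
#'
#' The ratio `(F_B + F_D) / F_S` of expected fixed nonsynonymous to
#' synonymous sites; `theta_s` cancels.  Converges to [dn_ds_limit()] as
#' `t_div` grows.
#'
#' @inheritParams expected_poly_sites
#' @return Expected dN/dS (scalar).
#' @export
dn_ds_expected <- function(params) {
  f <- expected_fixed_sites(params)
  unname((f[["F_B"]] + f[["F_D"]]) / f[["F_S"]])
}

#' Expected dN/dS in the long-divergence limit
#'
#' When the species diverged much longer ago than `Ne` generations the
#' boundary terms become negligible and dN/dS reduces to the
#' mutation-rate ratio times the average relative fixation rate:
#' `mu_ratio * (alpha_m * x / (1 - exp(-x)) + (1 - alpha_m) * (-x) / (1 - exp(x)))`
#' with `x = ne_s`.  Continuous at `x = 0` where it equals `mu_ratio`.
#' This is the default divergence observable for inference
#' (see [estimate_gene()]).
#'
#' @inheritParams expected_poly_sites
#' @return Expected dN/dS (scalar).
#' @export
dn_ds_limit <- function(params) {
  stopifnot(inherits(params, "prf_params"))
  .dn_ds_limit_raw(params$ne_s, params$alpha_m, params$mu_ratio)
}

## scalar core used by both the params API and the inference hot loop
.dn_ds_limit_raw <- function(gamma, alpha_m, mu_ratio) {
  mu_ratio * (alpha_m * .fix_factor(gamma) + (1 - alpha_m) * .fix_factor(-gamma))
}

## count-ratio pN/pS for signed gamma, alpha (inference hot loop)
.pn_ps_raw <- function(gamma, alpha_m, mu_ratio, m) {
  mu_ratio * (alpha_m * .poly_integral(gamma, m) +
                (1 - alpha_m) * .poly_integral(-gamma, m)) / .harmonic(m - 1)
}
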