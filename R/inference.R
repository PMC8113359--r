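#' Mutation-rate ratio from site counts
#'
#' Estimates the ratio of total nonsynonymous to synonymous mutation rates
#' of a gene as the ratio of its nonsynonymous to synonymous site counts
#' (equal per-site rates assumed).
#'
#' @param sites_n,sites_s Site totals; `sites_s` must be positive.
#' @return `sites_n / sites_s`.  A zero `sites_n` yields 0 with a warning
#'   (such a gene carries no information about selection on protein
#'   changes).
#' @export
estimate_mu_ratio <- function(sites_n, sites_s) {
  if (any(sites_s <= 0)) stop("'sites_s' must be positive")
  if (any(sites_n < 0)) stop("'sites_n' must be non-negative")
  if (any(sites_n == 0))
    warning("gene(s) with zero nonsynonymous sites are uninformative")
  sites_n / sites_s
}

## Coefficients (c_B, c_D) such that the model's expected dN/dS equals
## mu_ratio * (alpha * c_B + (1 - alpha) * c_D).  The long-divergence limit
## uses the relative fixation rates alone; the finite-t_div model folds in
## the boundary integrals.
.dn_coefs <- function(gamma, m, t_div = NULL) {
  fB <- .fix_factor(gamma)
  fD <- .fix_factor(-gamma)
  if (is.null(t_div)) return(c(fB, fD))
  denom <- t_div + 1 / m + 1
  c(fB * (t_div + g_integral(gamma, m) + g_integral(gamma, 1)) / denom,
    fD * (t_div + g_integral(-gamma, m) + g_integral(-gamma, 1)) / denom)
}

## Expected pN/pS divided by mu_ratio, optionally via a precomputed
## interpolator for the segregating-site integral.
.pn_model <- function(gamma, alpha, m, interp = NULL) {
  if (is.null(interp)) {
    JB <- .poly_integral(gamma, m)
    JD <- .poly_integral(-gamma, m)
  } else {
    JB <- interp(gamma)
    JD <- interp(-gamma)
  }
  (alpha * JB + (1 - alpha) * JD) / .harmonic(m - 1)
}

## Cubic-spline interpolator of the segregating-site integral J(gamma, m)
## on an asinh-transformed grid; used only for the coarse scan stage.
.make_poly_interp <- function(m, ne_s_max = 100) {
  gp <- 10^seq(-6, log10(ne_s_max), length.out = 121)
  grid <- c(-rev(gp), 0, gp)
  vals <- vapply(grid, .poly_integral, numeric(1), m = m)
  sf <- stats::splinefun(asinh(grid), vals, method = "natural")
  function(g) sf(asinh(g))
}

#' Estimate Ne*s and alpha_m for one gene
#'
#' Numerically inverts the PRF forward model: finds the scaled selection
#' strength `ne_s` and beneficial fraction `alpha_m` whose predicted pN/pS
#' and dN/dS best match the observed ratios, minimising the sum of squared
#' log residuals over `ne_s` in `[1e-6, 100]`, `alpha_m` in `[0, 1]`.
#' Both expected ratios are linear in `alpha_m` at fixed `ne_s`, so the fit
#' profiles `alpha_m` out of the dN/dS equation along a deterministic grid
#' in `log(ne_s)`, refines the profiled objective with bounded 1-d
#' optimisation, and finishes with a bounded joint polish; the procedure is
#' deterministic.
#'
#' Observations here are *count* ratios on the model's own scale
#' (segregating nonsynonymous over synonymous sites; fixed nonsynonymous
#' over synonymous sites), i.e. the quantities whose expectations are
#' [pn_ps_expected()] and [dn_ds_limit()].  The site-fraction form of
#' pN/pS (see [compute_pnps()]) differs by the factor
#' `sites_s / sites_n`, which cancels against `mu_ratio` when that is
#' estimated as `sites_n / sites_s`.
#'
#' Near-neutral data cannot pin down `alpha_m` (the two mutation classes
#' become indistinguishable): whenever the estimate of `ne_s` falls below
#' `1e-4` the result is flagged `neutral_alpha_unidentifiable`.
#' Observations of exactly zero are floored at a caller-supplied minimum
#' positive observable value and flagged `boundary`.  If no parameter pair
#' can approach the observations the minimal-residual estimate is returned
#' flagged `no_solution`.
#'
#' @param pnps_obs,dnds_obs Observed count ratios, finite and `>= 0`.
#' @param mu_ratio Mutation-rate ratio, e.g. from [estimate_mu_ratio()].
#' @param m Sample size in gene copies.
#' @param t_div Optional divergence time (units of `2 Ne` generations); when
#'   supplied the finite-divergence dN/dS model is inverted instead of the
#'   long-divergence limit.
#' @param pnps_floor,dnds_floor Replacement values used when the
#'   corresponding observation is 0 (half the smallest positive observable
#'   ratio is the intended choice; see [estimate_table()]).
#' @param n_grid Number of scan points in `log(ne_s)`.
#' @param tol Convergence tolerance on the residual norm.
#' @param .interp Optional precomputed interpolator (internal; built by
#'   [estimate_table()] to share across genes).
#' @return An object of class `prf_estimate`: list with `ne_s_hat`,
#'   `alpha_m_hat`, `converged`, `residual_norm` and `identifiability`
#'   (one of `ok`, `neutral_alpha_unidentifiable`, `boundary`,
#'   `no_solution`).
#' @export
estimate_gene <- function(pnps_obs, dnds_obs, mu_ratio, m, t_div = NULL,
                          pnps_floor = NULL, dnds_floor = NULL,
                          n_grid = 41, tol = 1e-5, .interp = NULL) {
  if (!is.finite(pnps_obs) || !is.finite(dnds_obs))
    stop("observed ratios must be finite numbers")
  if (pnps_obs < 0 || dnds_obs < 0) stop("observed ratios must be >= 0")
  boundary <- FALSE
  if (pnps_obs == 0) {
    if (is.null(pnps_floor))
      stop("pnps_obs is 0: supply 'pnps_floor' (half the minimal positive observable ratio)")
    pnps_obs <- pnps_floor; boundary <- TRUE
  }
  if (dnds_obs == 0) {
    if (is.null(dnds_floor))
      stop("dnds_obs is 0: supply 'dnds_floor' (half the minimal positive observable ratio)")
    dnds_obs <- dnds_floor; boundary <- TRUE
  }
  y1 <- pnps_obs / mu_ratio   # target for the segregating-site ratio
  y2 <- dnds_obs / mu_ratio   # target for the fixation ratio
  lo <- 1e-6; hi <- 100

  profile_alpha <- function(gamma) {
    cc <- .dn_coefs(gamma, m, t_div)
    if (abs(cc[1] - cc[2]) < 1e-12) return(0.5)
    min(max((y2 - cc[2]) / (cc[1] - cc[2]), 0), 1)
  }
  obj <- function(gamma, alpha, interp = NULL) {
    cc <- .dn_coefs(gamma, m, t_div)
    r1 <- log(.pn_model(gamma, alpha, m, interp)) - log(y1)
    r2 <- log(alpha * cc[1] + (1 - alpha) * cc[2]) - log(y2)
    val <- r1^2 + r2^2
    if (!is.finite(val)) return(1e10)   # keeps bounded optimisers in-domain
    val
  }
  prof_obj <- function(lg, interp = NULL) {
    g <- exp(lg)
    obj(g, profile_alpha(g), interp)
  }

  ## deterministic coarse scan in log(ne_s); every local minimum of the
  ## profiled objective is refined, because the two observed ratios do not
  ## always pin down a unique parameter pair (near the alpha_m = 0 boundary
  ## a second, slightly stronger-selection solution can fit exactly)
  lgrid <- seq(log(lo), log(hi), length.out = n_grid)
  scan <- vapply(lgrid, prof_obj, numeric(1), interp = .interp)
  is_locmin <- vapply(seq_len(n_grid), function(i) {
    (i == 1 || scan[i] <= scan[i - 1]) &&
      (i == n_grid || scan[i] <= scan[i + 1])
  }, logical(1))
  refine_one <- function(i) {
    bl <- lgrid[max(1, i - 1)]; bu <- lgrid[min(n_grid, i + 1)]
    opt <- stats::optimize(prof_obj, c(bl, bu), tol = 1e-10)
    lg <- opt$minimum
    a <- profile_alpha(exp(lg))
    ## joint polish on (log ne_s, alpha_m); exact integrals throughout
    polish <- stats::optim(c(lg, a), function(p) obj(exp(p[1]), p[2]),
                           method = "L-BFGS-B",
                           lower = c(log(lo), 0), upper = c(log(hi), 1),
                           control = list(factr = 10))
    if (polish$value <= obj(exp(lg), a)) {
      lg <- polish$par[1]; a <- polish$par[2]
    }
    c(lg = lg, a = a, val = obj(exp(lg), a))
  }
  cand <- vapply(which(is_locmin), refine_one, numeric(3))
  ## boundary branches: solve the dN/dS equation exactly at alpha_m = 0 or
  ## 1 (where the profile clips) and keep the solution if pN/pS also fits;
  ## this resolves the near-boundary ambiguity deterministically
  for (a_fix in c(0, 1)) {
    h <- function(lg) {
      cc <- .dn_coefs(exp(lg), m, t_div)
      (if (a_fix == 0) cc[2] else cc[1]) - y2
    }
    if (sign(h(log(lo))) != sign(h(log(hi)))) {
      rt <- stats::uniroot(h, c(log(lo), log(hi)), tol = 1e-12)
      cand <- cbind(cand, c(lg = rt$root, a = a_fix,
                            val = obj(exp(rt$root), a_fix)))
    }
  }
  fits <- which(sqrt(cand["val", ]) < tol)
  ## among (near-)exact fits prefer the weakest selection consistent with
  ## the data; otherwise take the minimal-residual candidate
  best <- if (length(fits)) fits[which.min(cand["lg", fits])]
          else which.min(cand["val", ])
  lg_hat <- cand["lg", best]
  a_hat <- min(max(cand["a", best], 0), 1)
  ne_s_hat <- min(max(exp(lg_hat), lo), hi)
  resid <- sqrt(cand["val", best])

  converged <- resid < tol
  flag <- if (ne_s_hat < 1e-4) "neutral_alpha_unidentifiable"
          else if (!converged) "no_solution"
          else if (boundary) "boundary"
          else "ok"
  structure(list(ne_s_hat = ne_s_hat, alpha_m_hat = a_hat,
                 converged = converged, residual_norm = resid,
                 identifiability = flag),
            class = "prf_estimate")
}

#' @export
print.prf_estimate <- function(x, ...) {
  cat(sprintf(
    "PRF estimate: Ne*s = %.6g, alpha_m = %.6g (%s, residual %.3g)\n",
    x$ne_s_hat, x$alpha_m_hat, x$identifiability, x$residual_norm))
  invisible(x)
}

#' Estimate Ne*s and alpha_m for every gene in a table
#'
#' Applies [estimate_gene()] gene by gene.  Observed count ratios are
#' formed as `poly_n / poly_s` and `div_n / div_s` (or, when divergence
#' counts are absent, by rescaling a `dn_ds` rate-ratio column by
#' `sites_n / sites_s`); `mu_ratio` is `sites_n / sites_s` per gene.
#' Genes whose ratios are undefined (`poly_s == 0`, or no usable
#' divergence) are skipped with the reason recorded in the `prf_flag`
#' column.  Zero numerators are floored at half the smallest positive
#' observable ratio for the gene's counts and flagged `boundary`.
#' Output is deterministic given the input table.
#'
#' @param genes Gene table (see [validate_gene_table()]); divergence enters
#'   through `div_n`/`div_s` count columns or a `dn_ds` column.
#' @param m Sample size in gene copies.
#' @param t_div Optional divergence time forwarded to [estimate_gene()].
#' @param verbose Emit a message summarising skipped genes.
#' @return The table with columns `ne_s_hat`, `alpha_m_hat`,
#'   `prf_residual` and `prf_flag` appended.
#' @export
estimate_table <- function(genes, m, t_div = NULL, verbose = TRUE) {
  validate_gene_table(genes)
  n <- nrow(genes)
  if (n == 0) stop("empty gene table")
  interp <- .make_poly_interp(m)
  ne_s_hat <- alpha_m_hat <- resid <- rep(NA_real_, n)
  flag <- rep(NA_character_, n)
  have_div_counts <- all(c("div_n", "div_s") %in% names(genes))
  if (!have_div_counts && !"dn_ds" %in% names(genes))
    stop("gene table needs 'div_n'/'div_s' counts or a 'dn_ds' column")
  for (i in seq_len(n)) {
    if (genes$poly_s[i] == 0 || is.na(genes$poly_s[i])) {
      flag[i] <- "skipped_undefined_pnps"
      next
    }
    mu_ratio <- genes$sites_n[i] / genes$sites_s[i]
    pnps <- genes$poly_n[i] / genes$poly_s[i]
    if (have_div_counts) {
      if (is.na(genes$div_s[i]) || genes$div_s[i] == 0) {
        flag[i] <- "skipped_undefined_dnds"
        next
      }
      dnds <- genes$div_n[i] / genes$div_s[i]
      dnds_floor <- 0.5 / genes$div_s[i]
    } else {
      if (is.na(genes$dn_ds[i])) {
        flag[i] <- "skipped_undefined_dnds"
        next
      }
      dnds <- genes$dn_ds[i] * mu_ratio
      dnds_floor <- 0.5 * mu_ratio / genes$sites_s[i]
    }
    est <- estimate_gene(pnps, dnds, mu_ratio, m, t_div = t_div,
                         pnps_floor = 0.5 / genes$poly_s[i],
                         dnds_floor = dnds_floor, .interp = interp)
    ne_s_hat[i] <- est$ne_s_hat
    alpha_m_hat[i] <- est$alpha_m_hat
    resid[i] <- est$residual_norm
    flag[i] <- est$identifiability
  }
  if (all(is.na(ne_s_hat))) stop("no gene had usable pN/pS and dN/dS observations")
  n_skip <- sum(startsWith(flag, "skipped"))
  if (verbose && n_skip > 0)
    message(n_skip, " gene(s) skipped: ",
            paste(names(table(flag[startsWith(flag, "skipped")])), collapse = ", "))
  genes$ne_s_hat <- ne_s_hat
  genes$alpha_m_hat <- alpha_m_hat
  genes$prf_residual <- resid
  genes$prf_flag <- flag
  genes
}
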