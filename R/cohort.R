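#' Configuration of a synthetic gene cohort
#'
#' Defines the generative model for cohorts with planted age-dependent
#' selection.  Each gene receives a true age-of-expression slope (REA)
#' drawn from a normal distribution; REA maps log-linearly to the scaled
#' selection strength (`ne_s = exp(a0 + a1 * rea)`) and logistically to the
#' beneficial fraction (`alpha_m = plogis(c0 + c1 * rea)`).  Expression is
#' simulated on the log scale (baseline + tissue offset + REA * age +
#' noise); polymorphism and divergence site counts are Poisson draws around
#' the PRF forward expectations; gene age is an exponential waiting time
#' whose mean is the lifespan model's expected extinction time at the
#' gene's fixation rates.
#'
#' Defaults describe the cohort used throughout the package's validation:
#' five adult sampling ages with three replicates in each of three tissues
#' (an insect-style whole-body design), late-expressed genes under weaker
#' purifying selection (`a1 = -0.5`) and with a modestly larger beneficial
#' fraction (`c1 = 1`, around a small baseline `plogis(-3)`), a gene of
#' 400 nonsynonymous and 150 synonymous sites, and a synonymous mutation
#' scale `theta_s = 5` giving of order twenty segregating synonymous sites
#' per gene in a sample of `m = 40` copies.
#'
#' @param n_genes Number of genes (>= 1).
#' @param ages Sampling ages (arbitrary time units, e.g. weeks).
#' @param n_replicates_per_age Replicates per age per tissue.
#' @param n_tissues Number of tissues.
#' @param rea_mean,rea_sd Distribution of true REA slopes.
#' @param expr_noise_sd Residual SD of log expression.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log
#'   expression (log-normal baseline expression).
#' @param tissue_sd SD of per-gene, per-tissue log-expression offsets
#'   (creates variation in tissue specificity).
#' @param a0,a1 Intercept and slope of the log-linear map REA -> `ne_s`.
#' @param c0,c1 Intercept and slope of the logistic map REA -> `alpha_m`.
#' @param sites_n,sites_s Nonsynonymous / synonymous site totals (>= 1).
#' @param theta_s Synonymous population mutation scale for the whole gene
#'   (`4 Ne muS * sites_s`), > 0.
#' @param m Sample size in gene copies (>= 2).
#' @param t_div Divergence time in units of `2 Ne` generations.
#' @param mu_ratio Override for the mutation-rate ratio; defaults to
#'   `sites_n / sites_s` (equal per-site rates).
#' @param k_loss Loss threshold of the lifespan walk used for gene ages.
#' @param age_rate_scale Proportionality constant between the lifespan
#'   model's expected extinction time and the mean of the exponential
#'   gene-age draw.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_genes = 2000,
                          ages = c(1, 2, 3, 4, 5),
                          n_replicates_per_age = 3,
                          n_tissues = 3,
                          rea_mean = 0, rea_sd = 1,
                          expr_noise_sd = 0.5,
                          baseline_mean = 5, baseline_sd = 1,
                          tissue_sd = 0.5,
                          a0 = 0.5, a1 = -0.5,
                          c0 = -3, c1 = 1,
                          sites_n = 400, sites_s = 150,
                          theta_s = 5,
                          m = 40,
                          t_div = 50,
                          mu_ratio = NULL,
                          k_loss = 10,
                          age_rate_scale = 1,
                          seed = 1) {
  cfg <- list(n_genes = n_genes, ages = ages,
              n_replicates_per_age = n_replicates_per_age,
              n_tissues = n_tissues, rea_mean = rea_mean, rea_sd = rea_sd,
              expr_noise_sd = expr_noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, tissue_sd = tissue_sd,
              a0 = a0, a1 = a1, c0 = c0, c1 = c1,
              sites_n = sites_n, sites_s = sites_s, theta_s = theta_s,
              m = m, t_div = t_div,
              mu_ratio = if (is.null(mu_ratio)) sites_n / sites_s else mu_ratio,
              k_loss = k_loss, age_rate_scale = age_rate_scale, seed = seed)
  .check_cfg <- function(ok, field, what) {
    if (!ok) stop("invalid cohort configuration: '", field, "' ", what)
  }
  .check_cfg(n_genes >= 1, "n_genes", "must be >= 1")
  .check_cfg(length(ages) >= 2 && all(is.finite(ages)) && all(ages >= 0),
             "ages", "needs >= 2 finite, non-negative ages")
  .check_cfg(n_replicates_per_age >= 1, "n_replicates_per_age", "must be >= 1")
  .check_cfg(n_tissues >= 1, "n_tissues", "must be >= 1")
  .check_cfg(rea_sd >= 0, "rea_sd", "must be >= 0")
  .check_cfg(expr_noise_sd >= 0, "expr_noise_sd", "must be >= 0")
  .check_cfg(sites_n >= 1, "sites_n", "must be >= 1")
  .check_cfg(sites_s >= 1, "sites_s", "must be >= 1")
  .check_cfg(theta_s > 0, "theta_s", "must be > 0")
  .check_cfg(m >= 2 && m == round(m), "m", "must be an integer >= 2")
  .check_cfg(t_div > 0, "t_div", "must be > 0")
  .check_cfg(cfg$mu_ratio > 0, "mu_ratio", "must be > 0")
  .check_cfg(k_loss >= 1 && k_loss == round(k_loss), "k_loss",
             "must be a positive integer")
  .check_cfg(age_rate_scale > 0, "age_rate_scale", "must be > 0")
  structure(cfg, class = "cohort_config")
}

## memoised forward expectations over the (usually all-distinct) per-gene
## (ne_s, alpha_m) values: integrals are computed once per unique ne_s
.forward_expectations <- function(ne_s, alpha_m, cfg) {
  ug <- unique(ne_s)
  idx <- match(ne_s, ug)
  JB <- vapply(ug, .poly_integral, numeric(1), m = cfg$m)
  JD <- vapply(-ug, .poly_integral, numeric(1), m = cfg$m)
  GBm <- vapply(ug, g_integral, numeric(1), n = cfg$m)
  GB1 <- vapply(ug, g_integral, numeric(1), n = 1)
  GDm <- vapply(-ug, g_integral, numeric(1), n = cfg$m)
  GD1 <- vapply(-ug, g_integral, numeric(1), n = 1)
  fB <- vapply(ug, .fix_factor, numeric(1))
  fD <- vapply(-ug, .fix_factor, numeric(1))
  muN <- cfg$theta_s * cfg$mu_ratio
  n_B <- muN * alpha_m * JB[idx]
  n_D <- muN * (1 - alpha_m) * JD[idx]
  n_S <- cfg$theta_s * .harmonic(cfg$m - 1)
  F_B <- muN * alpha_m * fB[idx] * (cfg$t_div + GBm[idx] + GB1[idx])
  F_D <- muN * (1 - alpha_m) * fD[idx] * (cfg$t_div + GDm[idx] + GD1[idx])
  F_S <- cfg$theta_s * (cfg$t_div + 1 / cfg$m + 1)
  list(n_B = n_B, n_D = n_D, n_S = n_S, F_B = F_B, F_D = F_D, F_S = F_S,
       fix_B = alpha_m * cfg$mu_ratio * fB[idx],
       fix_D = (1 - alpha_m) * cfg$mu_ratio * fD[idx])
}

#' Generate a synthetic cohort with planted age-dependent selection
#'
#' Draws a full cohort under the generative model described in
#' [cohort_config()]: a log-expression matrix with per-sample age and
#' tissue metadata, a per-gene table of Poisson-sampled polymorphism and
#' divergence counts, and a ground-truth table (columns prefixed `truth_`)
#' holding the planted REA, `ne_s`, `alpha_m`, the exact model expectations
#' of the count ratios, and the lifespan quantities behind each gene age.
#' Identical configurations (including the seed) give identical output.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `agesel_cohort` with elements `expression`
#'   (an [expr_matrix()]), `genes` (gene table `data.frame`) and `truth`
#'   (`data.frame`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  rea <- stats::rnorm(n, cfg$rea_mean, cfg$rea_sd)
  ne_s <- exp(cfg$a0 + cfg$a1 * rea)
  alpha_m <- stats::plogis(cfg$c0 + cfg$c1 * rea)

  ## --- expression matrix -------------------------------------------------
  design <- expand.grid(replicate = seq_len(cfg$n_replicates_per_age),
                        age = cfg$ages,
                        tissue = sprintf("t%02d", seq_len(cfg$n_tissues)),
                        stringsAsFactors = FALSE)
  n_samp <- nrow(design)
  sample_id <- sprintf("s%04d", seq_len(n_samp))
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  tissue_off <- matrix(stats::rnorm(n * cfg$n_tissues, 0, cfg$tissue_sd),
                       nrow = n)
  tissue_idx <- as.integer(factor(design$tissue))
  vals <- baseline +
    tissue_off[, tissue_idx, drop = FALSE] +
    outer(rea, design$age) +
    matrix(stats::rnorm(n * n_samp, 0, cfg$expr_noise_sd), nrow = n)
  dimnames(vals) <- list(gene_id, sample_id)
  samples <- data.frame(sample_id = sample_id, age = design$age,
                        tissue = design$tissue,
                        stringsAsFactors = FALSE)
  expression <- expr_matrix(vals, samples)

  ## --- Poisson site counts around the PRF expectations -------------------
  fw <- .forward_expectations(ne_s, alpha_m, cfg)
  poly_n <- pmin(stats::rpois(n, fw$n_B + fw$n_D), cfg$sites_n)
  poly_s <- pmin(stats::rpois(n, fw$n_S), cfg$sites_s)
  div_n <- stats::rpois(n, fw$F_B + fw$F_D)
  div_s <- stats::rpois(n, fw$F_S)

  ## --- gene age from the lifespan walk -----------------------------------
  ## Fixation rates are the PRF per-class relative rates; the expected
  ## extinction time uses the small-alpha lifespan approximation.
  rB <- fw$fix_B; rD <- fw$fix_D
  t_bar <- (cfg$k_loss / (rB + rD)) * (1 + 2 * rB / (rB + rD))
  gene_age <- stats::rexp(n, rate = 1 / (cfg$age_rate_scale * t_bar))

  genes <- data.frame(
    gene_id = gene_id,
    poly_n = poly_n, poly_s = poly_s,
    sites_n = cfg$sites_n, sites_s = cfg$sites_s,
    div_n = div_n, div_s = div_s,
    dn_ds = ifelse(div_s > 0,
                   (div_n / cfg$sites_n) / (div_s / cfg$sites_s), NA_real_),
    gene_age = gene_age,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = gene_id,
    truth_rea = rea,
    truth_ne_s = ne_s,
    truth_alpha_m = alpha_m,
    truth_pn_ps = (fw$n_B + fw$n_D) / fw$n_S,
    truth_dn_ds = (fw$F_B + fw$F_D) / fw$F_S,
    truth_r_b = rB, truth_r_d = rD,
    truth_t_bar = t_bar,
    truth_gene_age = gene_age,
    stringsAsFactors = FALSE)
  structure(list(expression = expression, genes = genes, truth = truth,
                 config = cfg),
            class = "agesel_cohort")
}

#' @export
print.agesel_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes, %d samples (seed %d)\n",
              nrow(x$genes), ncol(x$expression$values), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `expression.tsv`, `samples.tsv`, `genes.tsv` and `truth.tsv`
#' into a directory, in the formats the package's readers consume.
#'
#' @param cohort An `agesel_cohort` from [generate_cohort()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "agesel_cohort"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- file.path(outdir, c("expression.tsv", "samples.tsv",
                               "genes.tsv", "truth.tsv"))
  write_expression_matrix(cohort$expression, paths[1], paths[2])
  write_gene_table(cohort$genes, paths[3])
  .write_tsv(cohort$truth, paths[4])
  invisible(paths)
}

#' Generate paralog pairs from a synthetic cohort
#'
#' Generates a cohort under `config`, computes per-gene metrics, and joins
#' disjoint random pairs of genes into a paralog-pair table with `_a`/`_b`
#' suffixed per-member statistics (REA, mean expression, tau, pN/pS, dN/dS,
#' gene age).  Pair members are ordered by ascending gene id.  Because REA
#' is continuous, paired genes differ in REA almost surely.
#'
#' @param config A [cohort_config()] object.
#' @param n_pairs Number of pairs; at most `floor(n_genes / 2)`.
#' @return A `data.frame` paralog table (see [read_paralog_table()]).
#' @export
generate_paralog_pairs <- function(config, n_pairs) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_pairs < 1) stop("'n_pairs' must be >= 1")
  if (n_pairs > config$n_genes %/% 2)
    stop("'n_pairs' exceeds the number of disjoint pairs available (",
         config$n_genes %/% 2, ")")
  cohort <- generate_cohort(config)
  genes <- compute_gene_metrics(cohort$expression, cohort$genes)
  pick <- sample(nrow(genes), 2 * n_pairs)
  ia <- pick[seq_len(n_pairs)]
  ib <- pick[n_pairs + seq_len(n_pairs)]
  swap <- genes$gene_id[ia] > genes$gene_id[ib]
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  cols <- c("rea", "mean_expr", "tau", "pn_ps", "dn_ds", "gene_age")
  out <- data.frame(gene_a = genes$gene_id[ia], gene_b = genes$gene_id[ib],
                    stringsAsFactors = FALSE)
  for (cl in cols) {
    out[[paste0(cl, "_a")]] <- genes[[cl]][ia]
    out[[paste0(cl, "_b")]] <- genes[[cl]][ib]
  }
  out
}
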