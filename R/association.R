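#' Spearman rank correlation test
#'
#' Two-sided Spearman rank correlation with midranks for ties and no
#' multiple-testing correction — the package's canonical significance test
#' for associations with REA (the least-squares coefficients it accompanies
#' are descriptive).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped
#'   and at least 5 complete pairs are required.
#' @return A list with `rho`, `p`, and `n_used`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_used = length(x))
}

.collinear_columns <- function(fit) {
  names(stats::coef(fit))[is.na(stats::coef(fit))]
}

#' Regression of an evolutionary statistic on REA
#'
#' Fits `y = b0 + b1 * rea + b2 * mean_expr (+ further covariates) + e` by
#' ordinary least squares, with tissue (if a `tissue` column is present)
#' entered as fixed per-tissue intercepts.  Missing values are removed
#' listwise.  The REA coefficient `b1` is reported descriptively; the
#' accompanying significance is the two-sided Spearman rank correlation of
#' the response with REA, uncorrected for multiple tests.
#'
#' @param table Gene table containing `rea`, the response, and covariates.
#' @param response Name of the response column (e.g. `"dn_ds"`, `"pn_ps"`,
#'   `"gene_age"`, `"ne_s_hat"`).
#' @param covariates Character vector of covariate columns (default mean
#'   expression; add `"tau"` to control for expression breadth).
#' @return An object of class `association_result`: response name,
#'   coefficient vector (`b0`, `b1` = REA, covariates in order),
#'   `spearman_rho`, `p_value`, `n_used`.
#' @export
fit_rea_regression <- function(table, response,
                               covariates = c("mean_expr")) {
  needed <- c("rea", response, covariates)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  covariates <- setdiff(covariates, "tissue")
  has_tissue <- "tissue" %in% names(table) &&
    length(unique(table$tissue)) >= 2
  vars <- c(response, "rea", covariates, if (has_tissue) "tissue")
  dat <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  if (nrow(dat) < 10) stop("fewer than 10 complete observations")
  rhs <- c("rea", covariates, if (has_tissue) "factor(tissue)")
  fml <- stats::as.formula(paste(sprintf("`%s`", response), "~",
                                 paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  bad <- .collinear_columns(fit)
  if (length(bad))
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  sp <- spearman_test(dat[[response]], dat$rea)
  structure(list(response = response,
                 coefficients = stats::coef(fit),
                 b1 = unname(stats::coef(fit)[["rea"]]),
                 spearman_rho = sp$rho,
                 p_value = sp$p,
                 n_used = nrow(dat),
                 fit = fit),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "Association of %s with REA: b1 = %.4g, Spearman rho = %.4f, p = %.3g (n = %d)\n",
    x$response, x$b1, x$spearman_rho, x$p_value, x$n_used))
  invisible(x)
}

#' Paralog-pair contrasts of an evolutionary statistic on REA
#'
#' For each paralog pair computes the within-pair difference of a statistic
#' and of REA (oriented `b - a`, with members ordered by ascending gene id
#' so the sign convention is reproducible), and regresses the statistic's
#' difference on the REA difference with differences in mean expression and
#' tau as covariates when present.  The output is invariant to flipping
#' pair orientation, since both differences negate jointly.
#'
#' @param pairs Paralog table (see [read_paralog_table()]) with `_a`/`_b`
#'   suffixed columns for `rea` and `statistic`.
#' @param statistic Base name of the statistic column (e.g. `"dn_ds"`,
#'   `"pn_ps"`, `"gene_age"`).
#' @return An `association_result` whose `b1` is the slope of
#'   `delta(statistic)` on `delta(REA)`.
#' @export
paralog_contrasts <- function(pairs, statistic) {
  for (col in c("gene_a", "gene_b", "rea_a", "rea_b",
                paste0(statistic, c("_a", "_b")))) {
    if (!col %in% names(pairs)) stop("paralog table lacks column '", col, "'")
  }
  ## canonical orientation: gene_a < gene_b
  swap <- pairs$gene_a > pairs$gene_b
  if (any(swap)) {
    suff_a <- grep("_a$", names(pairs), value = TRUE)
    for (ca in suff_a) {
      cb <- sub("_a$", "_b", ca)
      if (cb %in% names(pairs)) {
        tmp <- pairs[[ca]][swap]
        pairs[[ca]][swap] <- pairs[[cb]][swap]
        pairs[[cb]][swap] <- tmp
      }
    }
  }
  d <- data.frame(
    d_stat = pairs[[paste0(statistic, "_b")]] - pairs[[paste0(statistic, "_a")]],
    d_rea = pairs$rea_b - pairs$rea_a)
  for (cov in c("mean_expr", "tau")) {
    ca <- paste0(cov, "_a"); cb <- paste0(cov, "_b")
    if (all(c(ca, cb) %in% names(pairs)))
      d[[paste0("d_", cov)]] <- pairs[[cb]] - pairs[[ca]]
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10) stop("fewer than 10 complete paralog pairs")
  if (all(d$d_rea == 0)) stop("all REA differences are zero")
  fit <- stats::lm(d_stat ~ ., data = d)
  bad <- .collinear_columns(fit)
  if (length(bad))
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  sp <- spearman_test(d$d_stat, d$d_rea)
  structure(list(response = paste0("delta_", statistic),
                 coefficients = stats::coef(fit),
                 b1 = unname(stats::coef(fit)[["d_rea"]]),
                 spearman_rho = sp$rho,
                 p_value = sp$p,
                 n_used = nrow(d),
                 fit = fit),
            class = "association_result")
}

#' Association between REA and a binary gene annotation
#'
#' Tests whether an annotation (e.g. adult-cancer-driver or
#' dominant-disease status) is associated with the age of expression:
#' Spearman rank correlation of the 0/1 indicator with REA, a two-sided
#' Wilcoxon rank-sum test comparing REA between annotated and unannotated
#' genes, and per-bin annotated fractions over equal-count REA bins (for
#' plotting the enrichment curve).
#'
#' @param table Gene table with `rea` and the annotation column.
#' @param annotation Name of a logical (or 0/1) column.
#' @param n_bins Number of equal-count REA bins (default 10).
#' @return A list with `spearman_rho`, `spearman_p`, `wilcoxon_p`,
#'   `n_used`, and `bins` (a `data.frame` with per-bin mean REA, size, and
#'   annotated fraction).
#' @export
binary_trait_association <- function(table, annotation, n_bins = 10) {
  if (!annotation %in% names(table))
    stop("annotation column '", annotation, "' not in table")
  ok <- is.finite(table$rea) & !is.na(table[[annotation]])
  rea <- table$rea[ok]
  flag <- as.logical(table[[annotation]][ok])
  if (!any(flag) || all(flag))
    stop("annotation '", annotation, "' has a single class")
  ind <- as.numeric(flag)
  ct <- suppressWarnings(stats::cor.test(ind, rea, method = "spearman"))
  wt <- suppressWarnings(stats::wilcox.test(rea[flag], rea[!flag],
                                            alternative = "two.sided"))
  ord <- order(rea)
  bin <- integer(length(rea))
  bin[ord] <- ceiling(seq_along(ord) * n_bins / length(ord))
  bins <- data.frame(
    bin = seq_len(n_bins),
    mean_rea = as.numeric(tapply(rea, bin, mean)),
    n = as.integer(tapply(rea, bin, length)),
    fraction = as.numeric(tapply(flag, bin, mean)))
  list(spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       wilcoxon_p = wt$p.value, n_used = length(rea), bins = bins)
}
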