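#' Regression of expression on age (REA)
#'
#' The per-gene REA statistic is the ordinary least-squares slope of log
#' expression on sample age, using every sample as a data point.  Positive
#' REA means the gene is expressed most strongly late in life, negative
#' means early.  Because expression is on the log scale, REA measures a
#' proportional change per unit age and is invariant to rescaling a gene's
#' absolute expression level.
#'
#' @param x An [expr_matrix()] object.
#' @param gene_id Gene identifier (a rowname of `x$values`).
#' @return The OLS slope (log-expression units per unit age).
#' @examples
#' # a gene rising linearly with age has REA equal to the line's slope
#' @export
compute_rea <- function(x, gene_id) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene_id %in% rownames(x$values)) stop("gene not found: ", gene_id)
  y <- x$values[gene_id, ]
  age <- x$samples$age
  ok <- !is.na(y)
  if (length(unique(age[ok])) < 2)
    stop("REA undefined for gene ", gene_id, ": fewer than 2 distinct ages")
  a <- age[ok] - mean(age[ok])
  sum(a * (y[ok] - mean(y[ok]))) / sum(a^2)
}

#' REA slopes for every gene at once
#'
#' Vectorised version of [compute_rea()] for complete matrices (the common
#' case); genes with missing values fall back to the per-gene path.
#'
#' @param x An [expr_matrix()] object.
#' @return Named numeric vector of slopes, one per gene.
#' @export
rea_slopes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  age <- x$samples$age
  if (length(unique(age)) < 2) stop("need >= 2 distinct sample ages")
  a <- age - mean(age)
  denom <- sum(a^2)
  if (!anyNA(x$values)) {
    ctr <- x$values - rowMeans(x$values)
    return(drop(ctr %*% a) / denom)
  }
  vapply(rownames(x$values), function(g) compute_rea(x, g), numeric(1))
}

#' Age of maximal expression
#'
#' The sampling age at which a gene's mean log expression is highest; an
#' alternative to REA for quantifying when in life a gene is expressed.
#' Ties are broken towards the youngest age.
#'
#' @inheritParams compute_rea
#' @return The age (same units as the sample metadata).
#' @export
age_of_max_expression <- function(x, gene_id) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene_id %in% rownames(x$values)) stop("gene not found: ", gene_id)
  y <- x$values[gene_id, ]
  means <- tapply(y, x$samples$age, mean, na.rm = TRUE)
  ages <- as.numeric(names(means))
  ord <- order(ages)
  ages <- ages[ord]; means <- means[ord]
  ages[which.max(means)]   # which.max returns the first (youngest) maximum
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / x_max) / (N - 1)` over per-tissue mean expression
#' values `x_i >= 0`: 0 for uniform expression across tissues, 1 for
#' expression confined to a single tissue.  Scale-invariant.
#'
#' @param per_tissue_means Non-negative numeric vector of per-tissue mean
#'   expression values (linear scale), length >= 2.
#' @return tau in `[0, 1]`.
#' @export
compute_tau <- function(per_tissue_means) {
  v <- per_tissue_means
  if (length(v) < 2) stop("tau requires at least 2 tissues")
  if (any(!is.finite(v)) || any(v < 0))
    stop("tau requires finite, non-negative expression values")
  mx <- max(v)
  if (mx == 0) stop("tau undefined: expression is zero in every tissue")
  sum(1 - v / mx) / (length(v) - 1)
}

#' Observed pN/pS from per-gene site counts
#'
#' The fraction of nonsynonymous sites segregating divided by the fraction
#' of synonymous sites segregating:
#' `(poly_n / sites_n) / (poly_s / sites_s)`.  When a gene has no
#' segregating synonymous sites the ratio is undefined and `NA` is returned
#' (such genes are excluded listwise from analyses that use pN/pS).
#'
#' @param poly_n,poly_s Counts of segregating nonsynonymous / synonymous
#'   sites (vectors recycle).
#' @param sites_n,sites_s Totals of nonsynonymous / synonymous sites,
#'   both `> 0`.
#' @return Numeric vector of ratios, `NA` where `poly_s == 0`.
#' @export
compute_pnps <- function(poly_n, poly_s, sites_n, sites_s) {
  if (any(c(poly_n, poly_s, sites_n, sites_s) < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (any(sites_n <= 0 | sites_s <= 0, na.rm = TRUE))
    stop("site totals must be positive")
  out <- (poly_n / sites_n) / (poly_s / sites_s)
  out[poly_s == 0] <- NA_real_
  out
}

#' Early/late age-of-expression classes from REA percentiles
#'
#' Labels each gene `early` (REA at or below the lower percentile cutoff),
#' `late` (at or above the upper cutoff) or `middle`.  Cutoffs use type-1
#' (inverse empirical CDF) quantiles, mirrored for the upper tail so the
#' two classes are symmetric: with distinct values and default percentiles,
#' `ceiling(n/10)` genes land in each extreme class.  Ties at a cutoff all
#' join the extreme class, keeping the rule deterministic.
#'
#' @param rea Numeric vector of REA values (length >= 10).
#' @param lower_pct,upper_pct Percentile bounds (defaults 10 and 90),
#'   `lower_pct < upper_pct`.
#' @return An object of class `age_classes`: list with factor `labels`
#'   (levels early/middle/late, in input order), `lower_cut`, `upper_cut`,
#'   and the percentile bounds.
#' @export
classify_age_groups <- function(rea, lower_pct = 10, upper_pct = 90) {
  if (lower_pct >= upper_pct)
    stop("'lower_pct' must be strictly less than 'upper_pct'")
  n <- length(rea)
  if (n < 10) stop("need at least 10 genes to form percentile classes")
  if (anyNA(rea)) stop("REA values must not be missing")
  if (length(unique(rea)) == 1)
    stop("all REA values are equal: age classes undefined")
  srt <- sort(rea)
  lower_cut <- srt[ceiling(n * lower_pct / 100)]
  upper_cut <- srt[n - ceiling(n * (100 - upper_pct) / 100) + 1]
  if (lower_cut >= upper_cut)
    stop("degenerate REA distribution: class cutoffs coincide")
  labels <- factor(ifelse(rea <= lower_cut, "early",
                          ifelse(rea >= upper_cut, "late", "middle")),
                   levels = c("early", "middle", "late"))
  structure(list(labels = labels, lower_cut = lower_cut,
                 upper_cut = upper_cut, lower_pct = lower_pct,
                 upper_pct = upper_pct),
            class = "age_classes")
}

#' @export
print.age_classes <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf(
    "Age-of-expression classes: %d early (REA <= %.4g), %d middle, %d late (REA >= %.4g)\n",
    tb[["early"]], x$lower_cut, tb[["middle"]], x$upper_cut))
  invisible(x)
}

#' Early/late contrast in dN/dS
#'
#' The proportional difference in mean dN/dS between late- and
#' early-expressed genes, normalised by the mean of the two class means:
#' `(mean_late - mean_early) / (0.5 * (mean_late + mean_early))`.
#' Bounded in `[-2, 2]` for non-negative ratios and antisymmetric under
#' swapping the classes.  Positive values mean relaxed purifying selection
#' on late genes.
#'
#' @param dn_ds Per-gene dN/dS values, aligned with `labels`.
#' @param labels An `age_classes` object (from [classify_age_groups()]).
#' @return The contrast statistic (scalar).
#' @export
delta_r_ns <- function(dn_ds, labels) {
  stopifnot(inherits(labels, "age_classes"))
  if (length(dn_ds) != length(labels$labels))
    stop("'dn_ds' and class labels differ in length")
  early <- dn_ds[labels$labels == "early"]
  late <- dn_ds[labels$labels == "late"]
  early <- early[!is.na(early)]
  late <- late[!is.na(late)]
  if (length(early) == 0 || length(late) == 0)
    stop("both the early and late class must contain genes with dN/dS")
  me <- mean(early); ml <- mean(late)
  if (me + ml == 0) stop("class means are both zero: contrast undefined")
  (ml - me) / (0.5 * (ml + me))
}

#' Per-gene expression metrics for a cohort
#'
#' Convenience pipeline: computes REA, mean log expression, tissue
#' specificity tau (from per-tissue means of linear-scale expression, when
#' a tissue column is present and names at least two tissues), observed
#' pN/pS, and the early/late age class for every gene, and appends them to
#' the gene table.
#'
#' @param x An [expr_matrix()] object.
#' @param genes A gene table (see [validate_gene_table()]); rows are matched
#'   to the matrix by `gene_id`.
#' @param lower_pct,upper_pct Percentiles for [classify_age_groups()].
#' @return The gene table with columns `rea`, `mean_expr`, `tau`, `pn_ps`
#'   and `age_class` added or replaced.
#' @export
compute_gene_metrics <- function(x, genes, lower_pct = 10, upper_pct = 90) {
  stopifnot(inherits(x, "expr_matrix"))
  validate_gene_table(genes)
  missing_genes <- setdiff(genes$gene_id, rownames(x$values))
  if (length(missing_genes))
    stop("genes absent from the expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  slopes <- rea_slopes(x)
  genes$rea <- unname(slopes[genes$gene_id])
  genes$mean_expr <- unname(rowMeans(x$values)[genes$gene_id])
  tissues <- x$samples$tissue
  if (!is.null(tissues) && length(unique(tissues)) >= 2) {
    lin <- exp(x$values)
    genes$tau <- vapply(genes$gene_id, function(g) {
      compute_tau(tapply(lin[g, ], tissues, mean))
    }, numeric(1))
  } else {
    genes$tau <- NA_real_
  }
  genes$pn_ps <- compute_pnps(genes$poly_n, genes$poly_s,
                              genes$sites_n, genes$sites_s)
  cls <- classify_age_groups(genes$rea, lower_pct, upper_pct)
  genes$age_class <- as.character(cls$labels)
  genes
}
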