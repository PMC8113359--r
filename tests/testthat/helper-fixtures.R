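# Shared fixture builders and brute-force oracles.

# Small expression matrix with explicit values: one row per gene,
# one sample per age (no replicates) unless a design is given.
make_expr <- function(values, ages, tissues = NULL) {
  values <- rbind(values)
  n_samp <- ncol(values)
  rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(n_samp))
  samples <- data.frame(sample_id = colnames(values), age = ages)
  if (!is.null(tissues)) samples$tissue <- tissues
  expr_matrix(values, samples)
}

# Minimal valid gene table.
make_gene_table <- function(n = 12, poly_n = 5, poly_s = 5,
                            sites_n = 100, sites_s = 50) {
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             poly_n = poly_n, poly_s = poly_s,
             sites_n = sites_n, sites_s = sites_s,
             stringsAsFactors = FALSE)
}

# Brute-force trapezoid quadrature oracle on a uniform grid; endpoint
# values must be supplied where the integrand formula is 0/0.
trapezoid <- function(f, a = 0, b = 1, n_panels = 1e6, ends = NULL) {
  x <- seq(a, b, length.out = n_panels + 1)
  y <- f(x)
  if (!is.null(ends)) {
    y[1] <- ends[1]
    y[n_panels + 1] <- ends[2]
  }
  sum((y[-1] + y[-length(y)]) / 2) * (b - a) / n_panels
}

# Independent evaluation of the expected segregating-site ratio:
# direct trapezoid quadrature of the sojourn-density integrands.
oracle_pnps <- function(ne_s, alpha_m, mu_ratio, m, n_panels = 1e6) {
  seg_integral <- function(g) {
    if (g == 0) {
      f <- function(p) (1 - p^m - (1 - p)^m) / p
      return(trapezoid(f, ends = c(m, 0), n_panels = n_panels))
    }
    u <- 4 * g
    f <- function(p) {
      (1 - exp(-u * (1 - p))) / ((1 - exp(-u)) * p * (1 - p)) *
        (1 - p^m - (1 - p)^m)
    }
    trapezoid(f, ends = c(m, 0), n_panels = n_panels)
  }
  hm <- sum(1 / seq_len(m - 1))
  mu_ratio * (alpha_m * seg_integral(ne_s) +
                (1 - alpha_m) * seg_integral(-ne_s)) / hm
}
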