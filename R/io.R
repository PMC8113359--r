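## Tabular I/O.  Canonical dialect: UTF-8 TSV with a header row, "NA" for
## missing values.  Readers validate loudly and never drop rows silently.

#' Expression matrix with per-sample metadata
#'
#' Container for a genes-by-samples matrix of log-expression values plus
#' per-sample metadata.  Every sample must have a finite, non-negative age;
#' tissue and sex labels are optional.  Values are stored on the (natural)
#' log scale; raw read counts are transformed as `log(count + pseudocount)`
#' on construction when `log_scale = FALSE` is declared by the caller.
#'
#' @param values Numeric matrix, rows = genes (rownames = gene ids),
#'   columns = samples (colnames = sample ids).
#' @param samples `data.frame` with columns `sample_id`, `age`, and
#'   optionally `tissue` and `sex`; one row per column of `values`.
#' @param log_scale Logical; `TRUE` if `values` are already
#'   log-transformed.  When `FALSE`, values are treated as raw counts and
#'   log-transformed.
#' @param pseudocount Pseudocount used when log-transforming raw counts.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, log_scale = TRUE, pseudocount = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  if (!is.data.frame(samples) || !all(c("sample_id", "age") %in% names(samples)))
    stop("'samples' must be a data.frame with columns 'sample_id' and 'age'")
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta))
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (anyNA(samples$age) || !is.numeric(samples$age) ||
      any(!is.finite(samples$age)) || any(samples$age < 0))
    stop("every sample needs a finite, non-negative 'age'")
  if (!log_scale) {
    if (any(values < 0, na.rm = TRUE))
      stop("raw counts must be non-negative")
    values <- log(values + pseudocount)
  }
  structure(list(values = values, samples = samples, log_scale = TRUE,
                 pseudocount = if (log_scale) NA_real_ else pseudocount),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (log scale)\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  ages: %s\n",
              paste(sort(unique(x$samples$age)), collapse = ", ")))
  if ("tissue" %in% names(x$samples))
    cat(sprintf("  tissues: %s\n",
                paste(unique(x$samples$tissue), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    comment.char = "")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The expression file has gene ids in the first column and one column per
#' sample; the metadata file is keyed by `sample_id` and must provide an
#' `age` for every sample.  Non-numeric expression cells and samples with
#' missing metadata are reported by name, never dropped.
#'
#' @param path Expression TSV (first column: gene id; remaining columns:
#'   one per sample).
#' @param metadata_path Sample metadata TSV with columns `sample_id`, `age`
#'   and optionally `tissue`, `sex`.
#' @param raw_counts If `TRUE` the file holds raw counts, which are
#'   log-transformed as `log(count + pseudocount)` on load.
#' @param pseudocount Pseudocount for the transform (default 1).
#' @return An [expr_matrix()] object.
#' @export
read_expression_matrix <- function(path, metadata_path, raw_counts = FALSE,
                                   pseudocount = 1) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2) stop("expression file needs a gene-id column plus samples")
  gene_ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf("non-numeric expression value at row %d, column '%s'",
                   bad, names(vals)[j]))
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- gene_ids
  meta <- .read_tsv(metadata_path)
  if (!all(c("sample_id", "age") %in% names(meta)))
    stop("metadata must have columns 'sample_id' and 'age'")
  expr_matrix(values, meta, log_scale = !raw_counts, pseudocount = pseudocount)
}

#' Write an expression matrix and its sample metadata to TSV
#'
#' Inverse of [read_expression_matrix()]; `write` then `read` reproduces
#' values to full printed precision.
#'
#' @param x An [expr_matrix()] object.
#' @param path,metadata_path Output TSV paths.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  .write_tsv(df, path)
  .write_tsv(x$samples, metadata_path)
  invisible(x)
}

.GENE_REQUIRED <- c("gene_id", "poly_n", "poly_s", "sites_n", "sites_s")

#' Validate a per-gene summary table
#'
#' Checks the schema used throughout the package: required columns
#' `gene_id`, `poly_n`, `poly_s`, `sites_n`, `sites_s`; counts must be
#' non-negative with `poly_n <= sites_n` and `poly_s <= sites_s`; optional
#' columns (`rea`, `mean_expr`, `tau`, `pn_ps`, `dn_ds`, `div_n`, `div_s`,
#' `gene_age`, annotation flags, ...) are tolerated and preserved.
#'
#' @param table A `data.frame`.
#' @return The table, invisibly, after validation.
#' @export
validate_gene_table <- function(table) {
  missing_cols <- setdiff(.GENE_REQUIRED, names(table))
  if (length(missing_cols))
    stop("gene table missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(table$gene_id))
    stop("duplicated gene ids in gene table")
  for (col in c("poly_n", "poly_s", "sites_n", "sites_s")) {
    if (any(table[[col]] < 0, na.rm = TRUE))
      stop("negative counts in column '", col, "'")
  }
  bad <- table$gene_id[which(table$poly_n > table$sites_n |
                               table$poly_s > table$sites_s)]
  if (length(bad))
    stop("polymorphic sites exceed site totals for genes: ",
         paste(bad, collapse = ", "))
  if ("tau" %in% names(table) &&
      any(table$tau < 0 | table$tau > 1, na.rm = TRUE))
    stop("'tau' must lie in [0, 1]")
  for (col in c("pn_ps", "dn_ds")) {
    if (col %in% names(table) && any(table[[col]] < 0, na.rm = TRUE))
      stop("'", col, "' must be >= 0 where present")
  }
  invisible(table)
}

#' Read / write a per-gene summary table
#'
#' @param path TSV path.
#' @return `read_gene_table`: a validated `data.frame`, one row per gene.
#' @seealso [validate_gene_table()] for the schema.
#' @export
read_gene_table <- function(path) {
  tab <- .read_tsv(path)
  tab$gene_id <- as.character(tab$gene_id)
  validate_gene_table(tab)
  tab
}

#' @rdname read_gene_table
#' @param table A gene table (`data.frame`).
#' @export
write_gene_table <- function(table, path) {
  validate_gene_table(table)
  .write_tsv(table, path)
  invisible(table)
}

#' Read / write a paralog-pair table
#'
#' Rows pair two distinct genes (`gene_a`, `gene_b`) and carry per-member
#' statistics in `_a` / `_b` suffixed columns (e.g. `rea_a`, `rea_b`).
#'
#' @param path TSV path.
#' @export
read_paralog_table <- function(path) {
  tab <- .read_tsv(path)
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("paralog table needs columns 'gene_a' and 'gene_b'")
  if (any(tab$gene_a == tab$gene_b))
    stop("paralog pairs must join two distinct genes")
  tab
}

#' @rdname read_paralog_table
#' @param table A paralog table (`data.frame`).
#' @export
write_paralog_table <- function(table, path) {
  if (any(table$gene_a == table$gene_b))
    stop("paralog pairs must join two distinct genes")
  .write_tsv(table, path)
  invisible(table)
}

#' Read a gene annotation list
#'
#' One gene id per line; `#` starts a comment; surrounding whitespace is
#' trimmed; duplicates are collapsed.  An empty result triggers a warning.
#'
#' @param path Text file path.
#' @return Character vector of unique gene ids.
#' @export
read_annotation_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  ids <- unique(trimws(lines))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0)
    warning("annotation list '", path, "' contains no gene ids")
  ids
}
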