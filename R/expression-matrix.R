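# ExpressionMatrix: gene x sample values with a declared quantification unit.

EXPR_UNITS <- c("count", "countNorm", "cpm", "tpm", "fpkm")

#' Construct an ExpressionMatrix
#'
#' A light container for a non-negative gene x sample expression table with
#' a declared quantification unit and, optionally, per-gene feature lengths
#' (in kilobases) needed for tpm conversion.  Gene and sample identifiers
#' live in the dimnames of `values`; duplicated gene ids are collapsed by
#' keeping the first occurrence.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must be
#'   non-negative with no missing entries.  Rownames are gene ids (generated
#'   as `gene1..geneN` when absent), colnames are sample ids.
#' @param unit one of `"count"`, `"countNorm"`, `"cpm"`, `"tpm"`, `"fpkm"`.
#' @param gene_lengths optional numeric vector of feature lengths in kb,
#'   named by gene id or aligned to the rows of `values`.
#' @return an object of class `ExpressionMatrix` with fields `values`,
#'   `unit` and `gene_lengths`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2), unit = "count")
#' dim(m$values)
expression_matrix <- function(values, unit = "count", gene_lengths = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  unit <- match.arg(unit, EXPR_UNITS)
  if (anyNA(values)) abort("expression values contain missing entries")
  if (any(values < 0)) abort("expression values must be non-negative")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    keep <- !duplicated(rownames(values))
    values <- values[keep, , drop = FALSE]
  }
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      gene_lengths <- gene_lengths[rownames(values)]
    }
    if (length(gene_lengths) != nrow(values) || anyNA(gene_lengths))
      abort("gene_lengths must cover every gene in the matrix")
    if (any(gene_lengths <= 0)) abort("gene_lengths must be positive (kb)")
    names(gene_lengths) <- rownames(values)
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [unit: %s]%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (is.null(x$gene_lengths)) "" else ", with gene lengths"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Filter low-abundance genes
#'
#' Keeps the genes whose expression strictly exceeds `min_expr` in at least
#' `min_samples` samples, e.g. the `(5, 10)` rule "more than 10 counts in at
#' least 5 samples".  The sample set is unchanged.  Default thresholds by
#' unit: 10 for counts, 1 for tpm/fpkm/cpm, and 10 for countNorm (count-scale).
#'
#' @param m an [expression_matrix()].
#' @param min_samples minimum number of samples passing the expression cut.
#' @param min_expr expression cutoff in the unit of `m`; `NULL` uses the
#'   unit default.
#' @return a filtered `ExpressionMatrix`.
#' @export
filter_low_abundance <- function(m, min_samples = 5L, min_expr = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!is_count1(min_samples)) abort("min_samples must be a positive integer")
  if (min_samples > ncol(m$values))
    abort("min_samples (%d) exceeds the number of samples (%d)",
          min_samples, ncol(m$values))
  if (is.null(min_expr)) {
    min_expr <- switch(m$unit, count = 10, countNorm = 10,
                       cpm = 1, tpm = 1, fpkm = 1)
  }
  keep <- rowSums(m$values > min_expr) >= min_samples
  expression_matrix(m$values[keep, , drop = FALSE], unit = m$unit,
                    gene_lengths = m$gene_lengths[keep])
}

#' Convert a count matrix between quantification units
#'
#' Per-sample transformations from raw counts:
#' \deqn{cpm_i = Count_i / \sum Count \times 10^6}
#' \deqn{countNorm_i = Count_i / \sum Count \times L_{Median}}
#' \deqn{tpm_i = \frac{Count_i / L_i}{\sum_{i'} Count_{i'} / L_{i'}} \times 10^6}
#' where \eqn{L_i} is the feature length and \eqn{L_{Median}} the median
#' library size across the samples of `m`.  Columns of cpm and tpm output
#' sum to \eqn{10^6}; countNorm columns sum to \eqn{L_{Median}}.
#'
#' @param m an [expression_matrix()] in count unit (the identity conversion
#'   is allowed for any unit).
#' @param target one of `"count"`, `"countNorm"`, `"cpm"`, `"tpm"`.
#' @return a converted `ExpressionMatrix`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(100, 300, 600), 3, 1), unit = "count")
#' convert_units(m, "cpm")$values[, 1]
convert_units <- function(m, target = c("cpm", "countNorm", "tpm", "count")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  target <- match.arg(target)
  if (target == m$unit) return(m)
  if (m$unit != "count")
    abort("conversions start from the count unit (have '%s')", m$unit)
  lib <- colSums(m$values)
  if (any(lib <= 0)) abort("sample with zero library size cannot be normalized")
  v <- switch(target,
    count = m$values,
    cpm = sweep(m$values, 2, lib, "/") * 1e6,
    countNorm = sweep(m$values, 2, lib, "/") * stats::median(lib),
    tpm = {
      if (is.null(m$gene_lengths))
        abort("gene_lengths are required for tpm conversion")
      rate <- m$values / m$gene_lengths
      sweep(rate, 2, colSums(rate), "/") * 1e6
    })
  expression_matrix(v, unit = target, gene_lengths = m$gene_lengths)
}

#' Read / write expression matrices as TSV with a YAML sidecar
#'
#' The table is gene x sample TSV with a header row of sample ids and the
#' first column `gene_id`.  Unit and gene lengths are carried in a sidecar
#' `<path>.yaml` metadata block so a round trip preserves the declared unit.
#'
#' @param m an [expression_matrix()].
#' @param path output TSV path.
#' @return `write_expression_matrix` returns `path` invisibly;
#'   `read_expression_matrix` returns an `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(unit = m$unit)
  if (!is.null(m$gene_lengths))
    meta$gene_lengths_kb <- as.list(stats::setNames(
      as.numeric(m$gene_lengths), names(m$gene_lengths)))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_expression_matrix
#' @param unit unit override when no sidecar is present.
#' @export
read_expression_matrix <- function(path, unit = "count") {
  df <- utils::read.delim(path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- as.character(df[[1]])
  lengths <- NULL
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$unit)) unit <- meta$unit
    if (!is.null(meta$gene_lengths_kb))
      lengths <- unlist(meta$gene_lengths_kb)
  }
  expression_matrix(v, unit = unit, gene_lengths = lengths)
}
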