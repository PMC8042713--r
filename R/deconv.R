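# Built-in NNLS deconvolution baseline and the adapter for external
# methods' proportion estimates.

#' Construct a ProportionEstimate
#'
#' @param values cell-type x sample matrix of estimated proportions;
#'   non-negative where not NA.
#' @param method_tag identifier of the producing method.
#' @param scale_claim `"relative"` (columns over non-NA entries sum to 1),
#'   `"absolute"` or `"unnormalized"`.
#' @return an object of class `ProportionEstimate` with an `na_mask` field
#'   marking failed estimates.
#' @export
proportion_estimate <- function(values, method_tag = "unknown",
                                scale_claim = c("relative", "absolute",
                                                "unnormalized")) {
  values <- as.matrix(values)
  scale_claim <- match.arg(scale_claim)
  na_mask <- is.na(values)
  if (any(values[!na_mask] < 0))
    abort("proportion estimates must be non-negative")
  if (scale_claim == "relative") {
    cs <- colSums(values, na.rm = TRUE)
    ok <- colSums(!na_mask) == 0L | abs(cs - 1) <= 1e-6  # all-NA cols exempt
    if (!all(ok))
      abort("relative estimates must have columns summing to 1")
  }
  if (is.null(rownames(values)))
    abort("estimates need cell-type rownames")
  structure(list(values = values, method_tag = method_tag,
                 scale_claim = scale_claim, na_mask = na_mask),
            class = "ProportionEstimate")
}

#' @export
print.ProportionEstimate <- function(x, ...) {
  cat(sprintf("ProportionEstimate [%s, %s]: %d cell types x %d samples (%d NA)\n",
              x$method_tag, x$scale_claim, nrow(x$values), ncol(x$values),
              sum(x$na_mask)))
  invisible(x)
}

#' Non-negative least squares deconvolution baseline
#'
#' Per sample, solves min ||R b - m||_2 subject to b >= 0 over the selected
#' genes and rescales b to sum to 1.  Both mixture and reference are
#' library-size normalized (counts-per-million scale) before fitting, which
#' makes the estimates invariant to the input quantification unit under
#' fixed library size.  No sum-to-one constraint is imposed inside the
#' solver; normalization is post hoc.
#'
#' @param mixture an [expression_matrix()] of heterogeneous samples.
#' @param reference an [expression_matrix()] with one column per cell type
#'   (at least 2).
#' @param genes optional gene ids (markers or signature) to restrict the
#'   fit; default all shared genes.
#' @return a [proportion_estimate()] with `method_tag = "builtin_nnls"` and
#'   `scale_claim = "relative"`.  A poorly conditioned reference triggers a
#'   warning but still returns the estimate.
#' @export
nnls_deconvolve <- function(mixture, reference, genes = NULL) {
  stopifnot(inherits(mixture, "ExpressionMatrix"),
            inherits(reference, "ExpressionMatrix"))
  if (ncol(reference$values) < 2L)
    abort("reference needs at least 2 cell types")
  shared <- intersect(rownames(mixture$values), rownames(reference$values))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) == 0L)
    abort("no genes shared between mixture, reference and gene list")
  cpm_scale <- function(v) sweep(v, 2, colSums(v), "/") * 1e6
  M <- cpm_scale(mixture$values)[shared, , drop = FALSE]
  R <- cpm_scale(reference$values)[shared, , drop = FALSE]
  kappa <- condition_number(R)
  if (!is.finite(kappa) || kappa > 1e8)
    warning(sprintf("reference is ill-conditioned (condition number %.3g)",
                    kappa))
  est <- apply(M, 2, function(m) {
    b <- tryCatch(pracma::lsqnonneg(R, m)$x,
                  error = function(e) rep(NA_real_, ncol(R)))
    if (anyNA(b) || sum(b) == 0) rep(NA_real_, ncol(R)) else b / sum(b)
  })
  rownames(est) <- colnames(R)
  proportion_estimate(est, method_tag = "builtin_nnls",
                      scale_claim = "relative")
}

#' Read external proportion estimates from TSV
#'
#' Expects cell-type rows and sample columns with a `cell_type` first
#' column; blank or NA cells are parsed into the NA mask.
#'
#' @param path TSV path.
#' @param method_tag method identifier recorded in the estimate.
#' @param cell_types optional expected roster; a mismatch errors with the
#'   symmetric difference listed.
#' @param scale_claim see [proportion_estimate()]; external outputs default
#'   to `"unnormalized"` since many tools do not guarantee sum-to-one.
#' @return a [proportion_estimate()].
#' @export
read_estimates <- function(path, method_tag, cell_types = NULL,
                           scale_claim = "unnormalized") {
  df <- utils::read.delim(path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df[[1]])
  if (!is.null(cell_types) && !setequal(rownames(v), cell_types)) {
    extra <- setdiff(rownames(v), cell_types)
    missing <- setdiff(cell_types, rownames(v))
    abort("cell-type roster mismatch: extra {%s}, missing {%s}",
          paste(extra, collapse = ", "), paste(missing, collapse = ", "))
  }
  proportion_estimate(v, method_tag = method_tag, scale_claim = scale_claim)
}
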