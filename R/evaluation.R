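# Dual-metric, dual-scale scoring of deconvolution estimates: Pearson r and
# mean absolute deviance per cell type, with NA penalties at the bounds.

#' Pearson correlation with NA on zero variance
#'
#' Standard sample correlation over samples; returns `NA` when either
#' vector is constant (the denominator of the correlation is zero), the
#' situation later caught by the evaluation penalty.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (length(x) < 2L) abort("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Mean absolute deviance
#'
#' `sum(|x_j - y_j|) / J`: the average absolute gap between estimated and
#' true proportions, sensitive to systematic offsets that correlation
#' cannot see.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative real (in \[0, 1\] for proportion inputs).
#' @export
mean_abs_dev <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  mean(abs(x - y))
}

#' Split a ground truth with unknown content into the two scales
#'
#' @param truth_with_unknown a [weight_matrix()] whose rows include exactly
#'   one unknown (e.g. tumor) component; columns sum to 1.
#' @param unknown_label row name of the unknown component (default: the
#'   `tumor_label` attribute set by [add_tumor_spikein()]).
#' @return list with `absolute` (known rows as-is; columns sum to 1 - t_j)
#'   and `relative` (known rows renormalized to column sum 1), both
#'   [weight_matrix()]-like matrices returned as plain matrices.
#' @export
ground_truth_scales <- function(truth_with_unknown, unknown_label = NULL) {
  stopifnot(inherits(truth_with_unknown, "WeightMatrix"))
  if (is.null(unknown_label))
    unknown_label <- attr(truth_with_unknown, "tumor_label")
  if (is.null(unknown_label) ||
      !unknown_label %in% truth_with_unknown$cell_types)
    abort("unknown component row not found in the ground truth")
  v <- truth_with_unknown$values
  known <- v[setdiff(rownames(v), unknown_label), , drop = FALSE]
  rel <- sweep(known, 2, colSums(known), "/")
  list(absolute = known, relative = rel)
}

#' Score an estimate against a ground truth, per cell type
#'
#' For each cell type, Pearson r and mAD are computed across samples
#' between the estimated and true proportions.  Any NA — whether returned
#' by the method or produced by a zero-variance correlation — is replaced
#' by the worst possible value, r = -1 and mAD = 1, so failures are
#' penalized rather than dropped.  An `"all"` row carries the unweighted
#' mean over cell types.
#'
#' @param est a [proportion_estimate()].
#' @param truth a [weight_matrix()] or plain cell-type x sample matrix of
#'   true proportions on the chosen scale.
#' @param scale label recorded in the output (`"relative"` or
#'   `"absolute"`).
#' @param condition optional named list of condition metadata columns
#'   (model, p_t, unit, K, regime, spike group, ...) replicated on each row.
#' @return data.frame with columns `method`, `scale`, `cell_type`, `r`,
#'   `mad`, plus any condition columns.
#' @export
evaluate_celltype <- function(est, truth, scale = "relative",
                              condition = list()) {
  stopifnot(inherits(est, "ProportionEstimate"))
  tv <- if (inherits(truth, "WeightMatrix")) truth$values else
    as.matrix(truth)
  if (!setequal(rownames(est$values), rownames(tv))) {
    extra <- setdiff(rownames(est$values), rownames(tv))
    missing <- setdiff(rownames(tv), rownames(est$values))
    abort("cell-type roster mismatch: extra {%s}, missing {%s}",
          paste(extra, collapse = ", "), paste(missing, collapse = ", "))
  }
  if (ncol(est$values) != ncol(tv))
    abort("estimate and truth must have the same samples")
  cts <- rownames(tv)
  rows <- lapply(cts, function(ct) {
    x <- est$values[ct, ]
    y <- tv[ct, ]
    if (anyNA(x)) {
      r <- -1; mad <- 1                 # method failure: maximal penalty
    } else {
      r <- pearson_r(x, y)
      if (is.na(r)) r <- -1             # zero-variance correlation
      mad <- mean_abs_dev(x, y)
    }
    data.frame(method = est$method_tag, scale = scale, cell_type = ct,
               r = r, mad = mad, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(method = est$method_tag, scale = scale,
                               cell_type = "all", r = mean(out$r),
                               mad = mean(out$mad),
                               stringsAsFactors = FALSE))
  for (nm in names(condition)) out[[nm]] <- condition[[nm]]
  out
}

#' Average evaluation results within condition groups
#'
#' Arithmetic mean of r and mAD within each combination of the grouping
#' keys; penalized -1 / 1 entries participate in the average rather than
#' being excluded.  The output is the long form of the method x condition
#' summary heatmaps.
#'
#' @param results row-bound output of [evaluate_celltype()].
#' @param over character vector of grouping column names (e.g.
#'   `c("method", "model")`); empty for a single global mean.
#' @return data.frame of group keys plus mean `r` and `mad`.
#' @export
summarize_results <- function(results, over = "method") {
  stopifnot(is.data.frame(results), all(c("r", "mad") %in% names(results)))
  missing <- setdiff(over, names(results))
  if (length(missing))
    abort("grouping keys not present: %s", paste(missing, collapse = ", "))
  if (length(over) == 0L)
    return(data.frame(r = mean(results$r), mad = mean(results$mad)))
  keys <- results[, over, drop = FALSE]
  agg <- stats::aggregate(results[, c("r", "mad")], by = keys, FUN = mean)
  agg[do.call(order, unname(as.list(agg[, over, drop = FALSE]))), ,
      drop = FALSE]
}

#' Rank methods per condition
#'
#' Within each condition, methods are ranked on the chosen metric — r
#' descending (higher is better), mAD ascending — with average ranks on
#' ties.
#'
#' @param summary output of [summarize_results()] containing a `method`
#'   column.
#' @param metric `"r"` or `"mad"`.
#' @param condition_keys columns defining a condition (default: everything
#'   except `method`, `r`, `mad`).
#' @return `summary` with an added `rank` column.
#' @export
rank_methods <- function(summary, metric = c("r", "mad"),
                         condition_keys = NULL) {
  metric <- match.arg(metric)
  if (!metric %in% names(summary)) abort("metric '%s' absent", metric)
  if (!"method" %in% names(summary)) abort("summary needs a method column")
  if (is.null(condition_keys))
    condition_keys <- setdiff(names(summary), c("method", "r", "mad", "rank"))
  if (length(condition_keys) == 0L) {
    grp <- rep(1L, nrow(summary))
  } else {
    grp <- interaction(summary[, condition_keys, drop = FALSE], drop = TRUE)
  }
  summary$rank <- stats::ave(
    if (metric == "r") -summary[[metric]] else summary[[metric]],
    grp, FUN = rank)
  summary
}
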