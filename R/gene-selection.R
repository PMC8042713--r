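# Marker-gene selection with percentile criteria and a relaxation loop;
# signature-gene selection from pairwise differential-expression results.

#' Marker selection criteria
#'
#' A gene is a marker of cell type T when its expression sits above the
#' `high_pct` percentile of the per-sample expression distribution in at
#' least a fraction `p` of T's samples, and below the `low_pct` percentile
#' in at least a fraction `p` of every other type's samples.  Starting from
#' `p = 0.95`, `p` is relaxed downwards in steps of `s` until every type has
#' at least `min_markers` markers.
#'
#' @param high_pct percentile for high expression in the targeted group
#'   (default 80).
#' @param low_pct percentile for low expression in other groups (default 50).
#' @param p initial required sample fraction (default 0.95).
#' @param s relaxation step (default 0.03).
#' @param min_markers minimum markers per type (default 2).
#' @return an object of class `MarkerCriteria`.
#' @export
marker_criteria <- function(high_pct = 80, low_pct = 50, p = 0.95, s = 0.03,
                            min_markers = 2L) {
  stopifnot(0 < low_pct, low_pct < high_pct, high_pct < 100,
            0 < s, s < p, p <= 1, is_count1(min_markers))
  structure(list(high_pct = high_pct, low_pct = low_pct, p = p, s = s,
                 min_markers = min_markers), class = "MarkerCriteria")
}

# markers of every type at one fixed sample fraction p
markers_at_p <- function(high_pass, low_pass, cell_types, p) {
  lapply(stats::setNames(cell_types, cell_types), function(ct) {
    others <- setdiff(cell_types, ct)
    ok <- high_pass[[ct]] >= p
    for (ot in others) ok <- ok & (low_pass[[ot]] >= p)
    names(which(ok))
  })
}

#' Select marker genes from purified replicates
#'
#' Percentile thresholds are computed per sample across genes (column-wise),
#' making the criterion rank-based and unit-invariant.  See
#' [marker_criteria()] for the selection rule and relaxation loop.
#'
#' @param replicates named list of per-cell-type [expression_matrix()]
#'   objects (or plain matrices) of purified samples, all on the same genes.
#' @param criteria a [marker_criteria()].
#' @return named list: marker gene ids per cell type.  The sample fraction
#'   at which selection succeeded is attached as attribute `p_final`.
#' @export
select_markers <- function(replicates, criteria = marker_criteria()) {
  stopifnot(length(replicates) >= 2L)
  mats <- lapply(replicates, function(r)
    if (inherits(r, "ExpressionMatrix")) r$values else as.matrix(r))
  genes <- rownames(mats[[1]])
  if (is.null(genes)) abort("replicate matrices need gene rownames")
  for (m in mats) if (!identical(rownames(m), genes))
    abort("replicate matrices must share the same genes")
  cell_types <- names(mats)
  # per type: fraction of samples where each gene clears the high / low bar
  high_pass <- lapply(mats, function(m) {
    thr <- apply(m, 2, stats::quantile, probs = criteria$high_pct / 100)
    rowMeans(sweep(m, 2, thr, ">"))
  })
  low_pass <- lapply(mats, function(m) {
    thr <- apply(m, 2, stats::quantile, probs = criteria$low_pct / 100)
    rowMeans(sweep(m, 2, thr, "<"))
  })
  p <- criteria$p
  repeat {
    sel <- markers_at_p(high_pass, low_pass, cell_types, p)
    if (all(lengths(sel) >= criteria$min_markers)) break
    p <- p - criteria$s
    if (p <= 0) {
      failing <- cell_types[lengths(sel) < criteria$min_markers]
      abort("no marker genes found for cell type(s): %s",
            paste(failing, collapse = ", "))
    }
  }
  attr(sel, "p_final") <- p
  sel
}

#' Default pairwise differential-expression test
#'
#' A deliberately simple built-in test: per gene, Welch's t-test on
#' log2(x + 1)-transformed, library-size-normalized (CPM) values, with
#' Benjamini-Hochberg adjustment across genes within the pair; log2FC is
#' the difference of group means of the transformed values.  Any external
#' per-gene DE table in the same schema can be used instead.
#'
#' @param replicates_a,replicates_b [expression_matrix()] (or matrix) of
#'   purified replicates for the two cell types; at least 2 samples each.
#' @param pair label for the pair (default `"a_vs_b"`).
#' @return data.frame with columns `pair`, `gene_id`, `log2fc`, `padj`.
#'   Zero-variance genes on both sides get `padj = NA` and are flagged via
#'   the `degenerate` attribute.
#' @export
de_test_default <- function(replicates_a, replicates_b, pair = "a_vs_b") {
  va <- if (inherits(replicates_a, "ExpressionMatrix")) replicates_a$values
        else as.matrix(replicates_a)
  vb <- if (inherits(replicates_b, "ExpressionMatrix")) replicates_b$values
        else as.matrix(replicates_b)
  if (ncol(va) < 2L || ncol(vb) < 2L)
    abort("each group needs at least 2 replicates")
  norm_log <- function(v) log2(sweep(v, 2, colSums(v), "/") * 1e6 + 1)
  la <- norm_log(va)
  lb <- norm_log(vb)
  n_a <- ncol(la); n_b <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va_ <- apply(la, 1, stats::var); vb_ <- apply(lb, 1, stats::var)
  se2 <- va_ / n_a + vb_ / n_b
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va_ / n_a)^2 / (n_a - 1) + (vb_ / n_b)^2 / (n_b - 1))
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval[se2 == 0 & ma == mb] <- 1        # identical constant groups
  pval[se2 == 0 & ma != mb] <- 0        # separated constant groups
  out <- data.frame(pair = pair, gene_id = rownames(la),
                    log2fc = ma - mb,
                    padj = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- all(se2 == 0)
  out
}

#' Run the default DE test on all cell-type pairs
#'
#' @param replicates named list of per-cell-type [expression_matrix()].
#' @return row-bound data.frame of [de_test_default()] results, one block
#'   per unordered pair.
#' @export
de_test_all_pairs <- function(replicates) {
  cts <- names(replicates)
  if (length(cts) < 2L) abort("need at least 2 cell types")
  pairs <- utils::combn(cts, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr)
    de_test_default(replicates[[pr[1]]], replicates[[pr[2]]],
                    pair = paste(pr, collapse = "_vs_"))))
}

#' Select signature genes from DE results
#'
#' Keeps the genes with `padj <= padj_max` and `|log2fc| >= lfc_min` in at
#' least one cell-type pair (`rule = "union"`, the default) or in every pair
#' (`rule = "intersection"`).
#'
#' @param de data.frame with columns `pair`, `gene_id`, `log2fc`, `padj`.
#' @param padj_max adjusted p-value cutoff (default 0.01).
#' @param lfc_min absolute log2 fold-change cutoff (default 10; a 1024-fold
#'   change — lower it for mild synthetic effects).
#' @param rule `"union"` or `"intersection"` across pairs.
#' @return character vector of signature gene ids.
#' @export
select_signature <- function(de, padj_max = 0.01, lfc_min = 10,
                             rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  if (is.null(de) || nrow(de) == 0L) abort("empty DE result")
  pass <- !is.na(de$padj) & de$padj <= padj_max & abs(de$log2fc) >= lfc_min
  if (rule == "union") return(sort(unique(de$gene_id[pass])))
  tab <- table(de$gene_id[pass])
  sort(names(tab)[tab == length(unique(de$pair))])
}
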