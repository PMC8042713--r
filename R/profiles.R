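# SourceProfiles: per-cell-type expected expression plus purified replicates.

#' Construct a SourceProfiles object
#'
#' Bundles per-cell-type mean expression (the S matrix of the mixing model
#' M = S x W + noise) with the purified replicate samples the means were, or
#' could be, derived from.
#'
#' @param mean_profiles numeric gene x cell-type matrix of expected
#'   expression; colnames are the cell-type labels.
#' @param replicates named list, one [expression_matrix()] of purified
#'   samples per cell type; every cell type needs at least one replicate.
#' @param dataset_tag provenance label for the dataset the profiles emulate.
#' @return an object of class `SourceProfiles`.
#' @export
source_profiles <- function(mean_profiles, replicates, dataset_tag = "synthetic") {
  mean_profiles <- as.matrix(mean_profiles)
  if (is.null(colnames(mean_profiles)))
    abort("mean_profiles must have cell-type colnames")
  cts <- colnames(mean_profiles)
  if (!setequal(names(replicates), cts))
    abort("replicates must cover exactly the cell types of mean_profiles")
  for (ct in cts) {
    r <- replicates[[ct]]
    if (!inherits(r, "ExpressionMatrix") || ncol(r$values) < 1L)
      abort("cell type '%s' needs at least one replicate sample", ct)
    if (!identical(rownames(r$values), rownames(mean_profiles)))
      abort("replicate genes of '%s' do not match mean_profiles", ct)
  }
  structure(list(mean_profiles = mean_profiles, cell_types = cts,
                 replicates = replicates[cts], dataset_tag = dataset_tag),
            class = "SourceProfiles")
}

#' @export
print.SourceProfiles <- function(x, ...) {
  cat(sprintf("SourceProfiles '%s': %d genes, %d cell types (%s)\n",
              x$dataset_tag, nrow(x$mean_profiles), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

# Shared "biology" of a synthetic source: baseline means plus a disjoint
# embedded marker set per cell type.  Kept separate from the replicate draw
# so several datasets can share it (the realistic cross-dataset setting).
profile_base <- function(n_genes, cell_types, marker_frac, marker_fold, seed) {
  K <- length(cell_types)
  n_markers <- floor(marker_frac * n_genes / K)
  if (n_markers < 2L) abort("marker budget too small: %.1f markers per type",
                            marker_frac * n_genes / K)
  with_seed(seed, {
    genes <- paste0("gene", seq_len(n_genes))
    # baseline expression: heavy-tailed log-normal, count-like scale
    base <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1.2)
    marker_idx <- split(seq_len(K * n_markers),
                        rep(seq_len(K), each = n_markers))
    S <- matrix(rep(base, K), ncol = K, dimnames = list(genes, cell_types))
    # mild type-specific variation on non-marker genes
    nonmark <- setdiff(seq_len(n_genes), unlist(marker_idx))
    S[nonmark, ] <- S[nonmark, ] *
      exp(matrix(stats::rnorm(length(nonmark) * K, sd = 0.15), ncol = K))
    # markers: high in the owner, exactly owner/marker_fold elsewhere.
    # Owner levels sit in the top percentiles of the baseline distribution:
    # an embedded marker is meant to be unambiguously highly expressed.
    for (k in seq_len(K)) {
      owner_level <- stats::rlnorm(n_markers, meanlog = log(3000), sdlog = 0.3)
      S[marker_idx[[k]], ] <- owner_level / marker_fold
      S[marker_idx[[k]], k] <- owner_level
    }
    gene_lengths <- exp(stats::runif(n_genes, log(0.5), log(10)))
    names(gene_lengths) <- genes
    markers <- lapply(marker_idx, function(i) genes[i])
    names(markers) <- cell_types
    list(S = S, markers = markers, gene_lengths = gene_lengths)
  })
}

# NB replicate draws around per-type means; size is the NB dispersion
# parameter (var = mu + mu^2/size).
draw_replicates <- function(S, n_replicates, size = 20) {
  lapply(stats::setNames(colnames(S), colnames(S)), function(ct) {
    mu <- S[, ct]
    v <- matrix(stats::rnbinom(length(mu) * n_replicates,
                               mu = rep(mu, n_replicates), size = size),
                ncol = n_replicates,
                dimnames = list(rownames(S),
                                paste0(ct, "_rep", seq_len(n_replicates))))
    expression_matrix(v, unit = "count")
  })
}

#' Generate synthetic purified source profiles
#'
#' Creates per-cell-type mean expression with an embedded, disjoint marker
#' set per type — each marker is expressed `marker_fold` times higher in its
#' owning type than in every other type — plus negative-binomial replicate
#' draws around the means, standing in for purified bulk RNA-seq datasets.
#' Gene lengths (kb) are drawn log-uniformly in \[0.5, 10\] for tpm support.
#'
#' @param n_genes number of genes (at least 10 per cell type).
#' @param cell_types character vector of cell-type labels.
#' @param marker_frac fraction of genes assigned as markers overall; each
#'   type owns `floor(marker_frac * n_genes / K)` markers (at least 2).
#' @param marker_fold owner-vs-other expression ratio of markers (>= 1).
#' @param n_replicates purified replicate samples per cell type.
#' @param seed integer seed; identical seeds give identical output.
#' @return a [source_profiles()] object with an extra `markers` field, the
#'   named list of embedded marker gene ids per cell type, and
#'   `gene_lengths`.
#' @export
#' @examples
#' src <- generate_source_profiles(300, c("T", "B", "mono"), seed = 1)
#' lengths(src$markers)
generate_source_profiles <- function(n_genes, cell_types, marker_frac = 0.02,
                                     marker_fold = 50, n_replicates = 5L,
                                     seed = 1L) {
  K <- length(cell_types)
  stopifnot(K >= 1L, is_count1(n_genes), is_count1(n_replicates),
            marker_fold >= 1, marker_frac > 0, marker_frac < 1)
  if (n_genes < 10L * K) abort("n_genes must be at least 10 per cell type")
  base <- profile_base(n_genes, cell_types, marker_frac, marker_fold, seed)
  reps <- with_seed(seed + 1L, draw_replicates(base$S, n_replicates))
  out <- source_profiles(base$S, reps, dataset_tag = sprintf("synthetic_s%d", seed))
  out$markers <- base$markers
  out$gene_lengths <- base$gene_lengths
  out
}

#' Generate several source datasets sharing the same underlying biology
#'
#' Emulates independent purified datasets of the same cell types (distinct
#' cohorts or labs): all datasets share one marker structure and baseline,
#' but each receives its own log-normal per-gene-per-type perturbation and
#' independent replicate draws.  Used by the mixture-vs-reference pairing
#' design, where mixtures and references may come from different datasets.
#'
#' @inheritParams generate_source_profiles
#' @param n_datasets number of independent datasets to emit.
#' @param dataset_jitter_sd sd (log scale) of the dataset-level perturbation.
#' @return a list of [source_profiles()] objects with distinct
#'   `dataset_tag`s and shared `markers`.
#' @export
generate_source_datasets <- function(n_datasets, n_genes, cell_types,
                                     marker_frac = 0.02, marker_fold = 50,
                                     n_replicates = 5L, dataset_jitter_sd = 0.1,
                                     seed = 1L) {
  stopifnot(is_count1(n_datasets))
  base <- profile_base(n_genes, cell_types, marker_frac, marker_fold, seed)
  lapply(seq_len(n_datasets), function(d) {
    ds_seed <- derive_seed(seed, sprintf("source_dataset/%d", d))
    with_seed(ds_seed, {
      S <- base$S * exp(matrix(stats::rnorm(length(base$S),
                                            sd = dataset_jitter_sd),
                               nrow = nrow(base$S)))
      dimnames(S) <- dimnames(base$S)
      reps <- draw_replicates(S, n_replicates)
      out <- source_profiles(S, reps,
                             dataset_tag = sprintf("synthetic_s%d_d%d", seed, d))
      out$markers <- base$markers
      out$gene_lengths <- base$gene_lengths
      out
    })
  })
}

#' Build a deconvolution reference from purified replicates
#'
#' Per-cell-type mean expression of the replicate samples, restricted to the
#' requested cell types.  Unknown components (e.g. a tumor spike-in line)
#' are excluded from references simply by leaving them out of `include`.
#'
#' @param src a [source_profiles()] object.
#' @param include cell types to keep (subset of `src$cell_types`); defaults
#'   to all of them.
#' @return an [expression_matrix()] with one column per included cell type.
#' @export
build_reference <- function(src, include = src$cell_types) {
  stopifnot(inherits(src, "SourceProfiles"))
  if (length(include) == 0L) abort("include must name at least one cell type")
  missing <- setdiff(include, src$cell_types)
  if (length(missing))
    abort("unknown cell types in include: %s", paste(missing, collapse = ", "))
  v <- vapply(include, function(ct) rowMeans(src$replicates[[ct]]$values),
              numeric(nrow(src$mean_profiles)))
  colnames(v) <- include
  expression_matrix(v, unit = src$replicates[[include[1]]]$unit)
}
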