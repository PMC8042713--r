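# Weight-matrix regimes (orthog / real / dominant / uniform) and tumor
# spike-ins.  All generators sample from uniform distributions and rescale
# every column to sum to 1.

#' Construct a WeightMatrix
#'
#' @param values K x J matrix of proportions; rownames are cell types.
#'   Every entry must lie in \[0, 1\] and every column must sum to 1
#'   (tolerance 1e-9).
#' @param regime one of `"orthog"`, `"real"`, `"dominant"`, `"uniform"`,
#'   `"custom"`.
#' @param seed seed recorded for provenance.
#' @return an object of class `WeightMatrix` with the 2-norm
#'   `condition_number` (ratio of largest to smallest singular value).
#' @export
weight_matrix <- function(values, regime = "custom", seed = NA_integer_) {
  values <- as.matrix(values)
  regime <- match.arg(regime,
                      c("orthog", "real", "dominant", "uniform", "custom"))
  if (anyNA(values) || any(values < 0) || any(values > 1))
    abort("weights must lie in [0, 1]")
  cs <- colSums(values)
  if (any(abs(cs - 1) > 1e-9)) abort("weight columns must sum to 1")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("type", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  structure(list(values = values, cell_types = rownames(values),
                 regime = regime, condition_number = condition_number(values),
                 seed = seed),
            class = "WeightMatrix")
}

#' @export
print.WeightMatrix <- function(x, ...) {
  cat(sprintf("WeightMatrix [%s]: %d cell types x %d samples, kappa = %.3g\n",
              x$regime, nrow(x$values), ncol(x$values), x$condition_number))
  invisible(x)
}

#' 2-norm condition number of a matrix
#'
#' Ratio of the largest to the smallest singular value; small values mean a
#' well-posed deconvolution system.
#'
#' @param m numeric matrix.
#' @return positive real (Inf when the smallest singular value is 0).
#' @export
condition_number <- function(m) {
  d <- svd(m, nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}

rescale_columns <- function(m) sweep(m, 2, colSums(m), "/")

#' "Orthog" regime: condition-number-optimized weight matrix
#'
#' Samples `n_candidates` K x J matrices with i.i.d. uniform entries,
#' rescales each column to sum to 1, and returns the candidate with the
#' smallest 2-norm condition number (ties broken by first index) — the
#' idealized, best-conditioned composition regime.
#'
#' @param K number of cellular components.
#' @param J number of samples (must be >= K).
#' @param n_candidates candidate matrices scanned (default 1000).
#' @param seed integer seed.
#' @param cell_types optional row labels.
#' @return a [weight_matrix()] with `regime = "orthog"`.
#' @export
make_orthog <- function(K, J, n_candidates = 1000L, seed = 1L,
                        cell_types = NULL) {
  stopifnot(is_count1(K), is_count1(J), is_count1(n_candidates))
  if (J < K) abort("J must be at least K for a full-rank weight matrix")
  best <- NULL
  best_kappa <- Inf
  with_seed(seed, {
    for (i in seq_len(n_candidates)) {
      w <- rescale_columns(matrix(stats::runif(K * J), K, J))
      kappa <- condition_number(w)
      if (kappa < best_kappa) {
        best_kappa <- kappa
        best <- w
      }
    }
  })
  if (!is.null(cell_types)) rownames(best) <- cell_types
  weight_matrix(best, regime = "orthog", seed = seed)
}

#' Default composition ranges of immune cell types in whole blood
#'
#' Plausible min/max proportion bands used by the `"real"` weight regime,
#' compiled from typical whole-blood composition; override freely.
#'
#' @return data.frame with columns `cell_type`, `min`, `max`.
#' @export
real_blood_ranges <- function() {
  data.frame(
    cell_type = c("neutrophils", "T", "CD4_T", "CD8_T", "B", "naive_B",
                  "memory_B", "NK", "monocytes", "eosinophils",
                  "myeloid_DC", "CD34_HSC"),
    min = c(0.50, 0.08, 0.04, 0.04, 0.02, 0.010, 0.010, 0.01, 0.02, 0.00,
            0.003, 0.001),
    max = c(0.70, 0.31, 0.20, 0.11, 0.07, 0.035, 0.035, 0.06, 0.10, 0.05,
            0.009, 0.010),
    stringsAsFactors = FALSE)
}

#' "Real" regime: weight matrix mimicking whole-blood composition
#'
#' Each component is sampled uniformly within its predefined \[min, max\]
#' band; of `n_candidates` sampled columns, the J whose pre-rescale sums are
#' closest to 1 are kept and rescaled to sum exactly to 1.  Columns whose
#' rescaled entries leave their band are resampled, so every returned entry
#' satisfies both the sum-to-1 and the range constraint.
#'
#' @inheritParams make_orthog
#' @param ranges data.frame with columns `cell_type`, `min`, `max` covering
#'   the requested cell types; defaults to [real_blood_ranges()].
#' @param cell_types the K cell types to include (default: first K rows of
#'   `ranges`).
#' @return a [weight_matrix()] with `regime = "real"`.
#' @export
make_real <- function(K, J, ranges = real_blood_ranges(),
                      cell_types = NULL, n_candidates = 1000L, seed = 1L) {
  stopifnot(is_count1(K), is_count1(J))
  if (is.null(cell_types)) cell_types <- ranges$cell_type[seq_len(K)]
  if (length(cell_types) != K) abort("cell_types must have length K")
  idx <- match(cell_types, ranges$cell_type)
  if (anyNA(idx))
    abort("ranges missing cell types: %s",
          paste(cell_types[is.na(idx)], collapse = ", "))
  lo <- ranges$min[idx]
  hi <- ranges$max[idx]
  if (any(lo > hi) || any(lo < 0) || any(hi > 1)) abort("invalid ranges")
  if (sum(lo) > 1 || sum(hi) < 1)
    abort("ranges cannot sum to 1 (min-sum %.3f, max-sum %.3f)",
          sum(lo), sum(hi))
  in_band <- function(col) all(col >= lo - 1e-12 & col <= hi + 1e-12)
  with_seed(seed, {
    draw <- function(n) matrix(stats::runif(K * n, lo, hi), nrow = K)
    cand <- draw(n_candidates)
    # columns ordered by |sum - 1|, ties by candidate index
    ord <- order(abs(colSums(cand) - 1), seq_len(ncol(cand)))
    accepted <- matrix(NA_real_, K, 0)
    for (j in ord) {
      col <- cand[, j] / sum(cand[, j])
      if (in_band(col)) accepted <- cbind(accepted, col)
      if (ncol(accepted) == J) break
    }
    tries <- 0L
    while (ncol(accepted) < J && tries < 1000L) {   # resample violators
      extra <- draw(n_candidates)
      ord <- order(abs(colSums(extra) - 1))
      for (j in ord) {
        col <- extra[, j] / sum(extra[, j])
        if (in_band(col)) accepted <- cbind(accepted, col)
        if (ncol(accepted) == J) break
      }
      tries <- tries + 1L
    }
    if (ncol(accepted) < J)
      abort("could not sample %d in-range columns; widen the ranges", J)
    rownames(accepted) <- cell_types
    colnames(accepted) <- NULL
    weight_matrix(accepted, regime = "real", seed = seed)
  })
}

#' "Dominant" regime: one major and K-1 minor components
#'
#' Per column, the major proportion is uniform in \[0.9, 0.99\] and each
#' minor is uniform in \[(1 - p_major)/(K - 1), (1 - p_major)/(K - 1) +
#' 0.01\]; the column is then rescaled to sum to 1.
#'
#' @inheritParams make_orthog
#' @param major_type label (or index) of the dominant component; default the
#'   first cell type.
#' @return a [weight_matrix()] with `regime = "dominant"`.
#' @export
make_dominant <- function(K, J, major_type = 1L, seed = 1L,
                          cell_types = NULL) {
  stopifnot(is_count1(K), is_count1(J))
  if (K < 2L) abort("the dominant regime needs at least 2 components")
  if (is.null(cell_types)) cell_types <- paste0("type", seq_len(K))
  major <- if (is.character(major_type)) match(major_type, cell_types)
           else as.integer(major_type)
  if (is.na(major) || major < 1L || major > K) abort("unknown major_type")
  with_seed(seed, {
    w <- matrix(NA_real_, K, J)
    for (j in seq_len(J)) {
      p_major <- stats::runif(1, 0.9, 0.99)
      band_lo <- (1 - p_major) / (K - 1)
      minors <- stats::runif(K - 1, band_lo, band_lo + 0.01)
      col <- numeric(K)
      col[major] <- p_major
      col[-major] <- minors
      w[, j] <- col / sum(col)
    }
    rownames(w) <- cell_types
    weight_matrix(w, regime = "dominant", seed = seed)
  })
}

#' "Uniform" regime: all components at a similar level
#'
#' Every entry is sampled uniformly in \[1/K, 1/K + 0.04\] and each column
#' rescaled to sum to 1, so per-column max/min ratios stay below
#' `(1/K + 0.04) / (1/K)`.
#'
#' @inheritParams make_orthog
#' @return a [weight_matrix()] with `regime = "uniform"`.
#' @export
make_uniform <- function(K, J, seed = 1L, cell_types = NULL) {
  stopifnot(is_count1(K), is_count1(J))
  if (is.null(cell_types)) cell_types <- paste0("type", seq_len(K))
  with_seed(seed, {
    w <- rescale_columns(matrix(stats::runif(K * J, 1 / K, 1 / K + 0.04),
                                K, J))
    rownames(w) <- cell_types
    weight_matrix(w, regime = "uniform", seed = seed)
  })
}

#' Tumor spike-in specification
#'
#' @param group spike-in band: `"small"` (tumor fraction 0.2-0.3), `"large"`
#'   (0.7-0.8), `"mosaic"` (0.05-0.95) or `"none"`.
#' @param range optional custom \[min, max\] overriding the group band.
#' @param tumor_label cell-type name of the unknown component.
#' @param mode `"final_fraction"` (immune weights scaled by 1 - t, tumor set
#'   to t, so the tumor fraction lands exactly in the advertised band) or
#'   `"append_rescale"` (t appended then the whole column rescaled by
#'   1/(1 + t)).
#' @return an object of class `SpikeSpec`.
#' @export
spike_spec <- function(group = c("small", "large", "mosaic", "none"),
                       range = NULL, tumor_label = "HCT116",
                       mode = c("final_fraction", "append_rescale")) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  if (is.null(range))
    range <- switch(group, small = c(0.2, 0.3), large = c(0.7, 0.8),
                    mosaic = c(0.05, 0.95), none = c(0, 0))
  if (group != "none" &&
      !(length(range) == 2L && range[1] >= 0 && range[1] < range[2] &&
        range[2] <= 1))
    abort("range must satisfy 0 <= min < max <= 1")
  structure(list(group = group, range = range, tumor_label = tumor_label,
                 mode = mode), class = "SpikeSpec")
}

#' Add a tumor (unknown-content) spike-in to a weight matrix
#'
#' Per column a tumor fraction t is drawn uniformly from the spike band and
#' combined with the immune weights according to `spec$mode`; either way the
#' returned K+1-row columns sum to 1, and the relative (renormalized
#' immune-only) proportions are unchanged.
#'
#' @param w a [weight_matrix()] of known (immune) components.
#' @param spec a [spike_spec()]; `group = "none"` passes `w` through with a
#'   zero tumor row.
#' @param seed integer seed.
#' @return a [weight_matrix()] with the tumor row appended, regime
#'   `"custom"`, and an attribute `tumor_fraction` holding the final
#'   per-sample tumor fractions.
#' @export
add_tumor_spikein <- function(w, spec, seed = 1L) {
  stopifnot(inherits(w, "WeightMatrix"), inherits(spec, "SpikeSpec"))
  if (spec$tumor_label %in% w$cell_types)
    abort("tumor label '%s' already present in the weight matrix",
          spec$tumor_label)
  J <- ncol(w$values)
  t_raw <- if (spec$group == "none") rep(0, J) else
    with_seed(seed, stats::runif(J, spec$range[1], spec$range[2]))
  if (spec$mode == "final_fraction" || spec$group == "none") {
    t_final <- t_raw
    known <- sweep(w$values, 2, 1 - t_final, "*")
  } else {  # append t then rescale the whole column by 1/(1 + t)
    t_final <- t_raw / (1 + t_raw)
    known <- sweep(w$values, 2, 1 + t_raw, "/")
  }
  v <- rbind(known, t_final)
  rownames(v) <- c(w$cell_types, spec$tumor_label)
  out <- weight_matrix(v, regime = "custom", seed = seed)
  attr(out, "tumor_fraction") <- t_final
  attr(out, "tumor_label") <- spec$tumor_label
  out
}
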