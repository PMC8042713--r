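# Variance-structure diagnostics for simulation realism: mean-variance
# trend, CV distribution, and sample-sample concordance, run in count unit.

#' Per-gene mean-variance table and log-log slope
#'
#' Computes the mean and variance of each gene across samples and fits an
#' ordinary least-squares slope of log10(variance) on log10(mean) over
#' genes with mean >= 1 and positive variance.  Poisson-like data give a
#' slope near 1; overdispersed gamma-Poisson data push the slope towards 2
#' (variance growing with the square of the mean).
#'
#' @param m an [expression_matrix()] (count-like unit) with >= 3 samples.
#' @return list with `table` (data.frame gene, mean, variance) and `slope`
#'   (NA when fewer than 2 usable genes).
#' @export
mean_variance_table <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 3L) abort("need at least 3 samples")
  mu <- rowMeans(m$values)
  v <- apply(m$values, 1, stats::var)
  tab <- data.frame(gene = rownames(m$values), mean = mu, variance = v,
                    stringsAsFactors = FALSE)
  use <- mu >= 1 & v > 0
  slope <- if (sum(use) < 2L) NA_real_ else
    unname(stats::coef(stats::lm(log10(v[use]) ~ log10(mu[use])))[2])
  list(table = tab, slope = slope)
}

# count kernel-density modes with topographic prominence >= frac * peak;
# tiny tail wiggles of the estimate do not count as modes
count_density_modes <- function(x, frac = 0.1, n_grid = 512L) {
  y <- stats::density(x, n = n_grid)$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(locmax) <= 1L) return(length(locmax))
  thr <- frac * max(y)
  n <- 0L
  for (i in locmax) {
    h <- y[i]
    saddles <- numeric(0)
    left <- y[seq_len(i - 1L)]
    hi_l <- which(left > h)
    if (length(hi_l)) saddles <- c(saddles, min(left[max(hi_l):(i - 1L)]))
    right <- y[seq(i + 1L, length(y))]
    hi_r <- which(right > h)
    if (length(hi_r)) saddles <- c(saddles, min(right[seq_len(min(hi_r))]))
    prom <- if (length(saddles)) h - max(saddles) else h
    if (prom >= thr) n <- n + 1L
  }
  n
}

#' Per-gene coefficient of variation and density-shape summary
#'
#' CV = sd/mean per gene with positive mean; all-zero genes are excluded
#' and counted.  The summary reports the median CV and a mode count of the
#' CV kernel density (512-point grid) where only maxima with topographic
#' prominence of at least 10 percent of the peak density count — a testable
#' proxy for the unimodal bell shape expected of realistic simulations that
#' is robust to tail wiggles of the density estimate.
#'
#' @param m an [expression_matrix()].
#' @return list with `cv` (named vector), `median_cv`, `n_modes`,
#'   `n_excluded`.
#' @export
cv_table <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mu <- rowMeans(m$values)
  keep <- mu > 0
  cv <- apply(m$values[keep, , drop = FALSE], 1, stats::sd) / mu[keep]
  n_modes <- if (length(cv) >= 10L) count_density_modes(cv) else NA_integer_
  list(cv = cv, median_cv = stats::median(cv), n_modes = n_modes,
       n_excluded = sum(!keep))
}

#' Pairwise sample concordance
#'
#' Spearman correlation (rank-based, so invariant to monotone per-sample
#' transforms) and Euclidean distance for every unordered sample pair.
#'
#' @param m an [expression_matrix()] with >= 2 samples.
#' @return list of two symmetric matrices, `spearman` (unit diagonal) and
#'   `euclidean` (zero diagonal).
#' @export
pairwise_sample_stats <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 2L) abort("need at least 2 samples")
  sp <- stats::cor(m$values, method = "spearman")
  eu <- as.matrix(stats::dist(t(m$values)))
  list(spearman = sp, euclidean = eu)
}

#' One-call variance report
#'
#' Convenience wrapper bundling [mean_variance_table()], [cv_table()] and
#' [pairwise_sample_stats()].
#'
#' @param m an [expression_matrix()].
#' @return list with elements `mean_variance`, `cv`, `pairs`.
#' @export
variance_report <- function(m) {
  list(mean_variance = mean_variance_table(m), cv = cv_table(m),
       pairs = pairwise_sample_stats(m))
}
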