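# The three simulation/noise models: normal, log-normal, gamma-Poisson (nb).

#' Noise specification
#'
#' Parameters of the sample-to-sample noise added on top of the expected
#' mixture S x W.  The perturbation level `p_t` walks a 10-element grid per
#' model — \{0, 0.1, ..., 0.9\} for the normal and log-normal models,
#' \{0.1, ..., 1\} for the negative binomial model (see [pt_grid()]) — but
#' any value in \[0, 1\] is accepted in free mode.
#'
#' @param model `"normal"`, `"lognormal"` or `"nb"`.
#' @param p_t perturbation level in \[0, 1\].
#' @param sigma constant noise multiplier of the normal / log-normal models
#'   (default 10); the noise sd is `sigma * p_t` on the log2 scale.
#' @param library_size expected reads per sample for the nb model; scalar or
#'   one value per sample, each at least 1e4.  Default 12e6.
#' @param normal_scale whether the second argument of the printed normal
#'   distributions is read as standard deviation (`"sd"`, default) or
#'   variance (`"var"`).
#' @param delta_sd sd of the per-gene log dispersion jitter delta in the nb
#'   model (default 0.5, i.e. variance 0.25).
#' @param delta_per draw delta once per `"gene"` (default; dispersion as a
#'   gene property) or per `"cell"` (gene x sample).
#' @param subtract_pseudocount if `TRUE`, the +1 pseudocount of the normal
#'   and log-normal formulas is removed after perturbation so the zero-noise
#'   limit returns S x W instead of S x W + 1.  Default `FALSE` (verbatim
#'   formulas).
#' @param seed optional integer seed applied by the perturbation functions.
#' @return an object of class `NoiseSpec`.
#' @export
noise_spec <- function(model = c("nb", "normal", "lognormal"), p_t = 0.1,
                       sigma = 10, library_size = 12e6,
                       normal_scale = c("sd", "var"), delta_sd = 0.5,
                       delta_per = c("gene", "cell"),
                       subtract_pseudocount = FALSE, seed = NULL) {
  model <- match.arg(model)
  normal_scale <- match.arg(normal_scale)
  delta_per <- match.arg(delta_per)
  stopifnot(is.numeric(p_t), length(p_t) == 1L, p_t >= 0, p_t <= 1,
            sigma > 0, delta_sd >= 0)
  if (any(library_size < 1e4))
    abort("library_size must be at least 1e4 reads")
  structure(list(model = model, p_t = p_t, sigma = sigma,
                 library_size = library_size, normal_scale = normal_scale,
                 delta_sd = delta_sd, delta_per = delta_per,
                 subtract_pseudocount = subtract_pseudocount, seed = seed),
            class = "NoiseSpec")
}

#' The 10-level perturbation grid of a noise model
#'
#' @param model `"normal"`, `"lognormal"` or `"nb"`.
#' @return numeric vector of 10 perturbation levels.
#' @export
pt_grid <- function(model = c("nb", "normal", "lognormal")) {
  model <- match.arg(model)
  if (model == "nb") seq(0.1, 1, by = 0.1) else seq(0, 0.9, by = 0.1)
}

# effective sd of the N(0, .) terms under the chosen scale convention
noise_sd <- function(spec) {
  s <- spec$sigma * spec$p_t
  if (spec$normal_scale == "var") sqrt(s) else s
}

check_nonneg <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || any(x < 0)) abort("expected matrix must be non-negative")
  x
}

#' Multiplicative (normal-model) perturbation
#'
#' Applies `m = 2 ^ (log2(x + 1) + z)`, `z ~ N(0, sigma * p_t)`, entrywise:
#' Gaussian noise on the log2 scale around the pseudocounted expected value.
#' Output is strictly positive; at `p_t = 0` it equals `x + 1` exactly.
#'
#' @param expected non-negative numeric matrix (expected mixture S x W).
#' @param spec a [noise_spec()] with `model = "normal"`.
#' @return perturbed matrix, same shape as `expected`.
#' @export
perturb_normal <- function(expected, spec) {
  stopifnot(inherits(spec, "NoiseSpec"))
  if (spec$model != "normal") abort("spec$model must be 'normal'")
  x <- check_nonneg(expected)
  with_seed(spec$seed, {
    z <- matrix(stats::rnorm(length(x), sd = noise_sd(spec)), nrow = nrow(x))
    out <- 2^(log2(x + 1) + z)
    if (spec$subtract_pseudocount) out <- pmax(out - 1, 0)
    dimnames(out) <- dimnames(x)
    out
  })
}

#' Additive (log-normal-model) perturbation
#'
#' Applies `m = x + 2^z`, `z ~ N(0, sigma * p_t)`: a log-normally
#' distributed positive error added to the expected value.  At `p_t = 0` the
#' added term is exactly 1.
#'
#' @inheritParams perturb_normal
#' @param spec a [noise_spec()] with `model = "lognormal"`.
#' @return perturbed matrix, entrywise no smaller than `expected`.
#' @export
perturb_lognormal <- function(expected, spec) {
  stopifnot(inherits(spec, "NoiseSpec"))
  if (spec$model != "lognormal") abort("spec$model must be 'lognormal'")
  x <- check_nonneg(expected)
  with_seed(spec$seed, {
    z <- matrix(stats::rnorm(length(x), sd = noise_sd(spec)), nrow = nrow(x))
    out <- x + 2^z
    if (spec$subtract_pseudocount) out <- pmax(out - 1, 0)
    dimnames(out) <- dimnames(x)
    out
  })
}

#' Gamma-Poisson (negative binomial) count simulation
#'
#' Two-layer count model: per gene i the expected count is
#' `mu_i0 = r_i * L_j`; a gamma draw with shape `1 / sigma_i^2` and mean
#' `mu_i0` models biological variance, and a Poisson draw around the gamma
#' mean models technical variance.  The dispersion follows
#' `sigma_i = (1.8 * p_t + 1 / sqrt(mu_i0)) * exp(delta / 2)` with
#' `delta ~ N(0, sd = delta_sd)` drawn once per gene by default, so `p_t`
#' tunes biological overdispersion on top of the Poisson floor.
#'
#' @param feature_props length-N non-negative vector of expected feature
#'   proportions, summing to 1 (tolerance 1e-8).
#' @param spec a [noise_spec()] with `model = "nb"`; `spec$library_size` may
#'   be a scalar or one value per sample.
#' @param n_samples number of samples (columns) to draw.
#' @param delta optional fixed per-gene delta vector (overrides the random
#'   draw; used for variance diagnostics).
#' @return integer count matrix, N x n_samples.
#' @export
#' @examples
#' r <- rep(1 / 100, 100)
#' v <- simulate_nb_counts(r, noise_spec("nb", p_t = 0.1,
#'                                       library_size = 1e4, seed = 1), 5)
#' colSums(v) # close to 1e4
simulate_nb_counts <- function(feature_props, spec, n_samples,
                               delta = NULL) {
  stopifnot(inherits(spec, "NoiseSpec"), is_count1(n_samples))
  if (spec$model != "nb") abort("spec$model must be 'nb'")
  r <- as.numeric(feature_props)
  if (any(r < 0)) abort("feature proportions must be non-negative")
  if (abs(sum(r) - 1) > 1e-8) abort("feature proportions must sum to 1")
  N <- length(r)
  L <- spec$library_size
  if (length(L) == 1L) L <- rep(L, n_samples)
  if (length(L) != n_samples)
    abort("library_size must be scalar or one value per sample")
  with_seed(spec$seed, {
    mu0 <- outer(r, L)                       # N x J expected counts
    if (is.null(delta)) {
      delta <- if (spec$delta_per == "gene") {
        matrix(rep(stats::rnorm(N, sd = spec$delta_sd), n_samples), nrow = N)
      } else {
        matrix(stats::rnorm(N * n_samples, sd = spec$delta_sd), nrow = N)
      }
    } else {
      delta <- matrix(rep(delta, length.out = N), nrow = N, ncol = n_samples)
    }
    sig <- (1.8 * spec$p_t + 1 / sqrt(mu0)) * exp(delta / 2)
    shape <- 1 / sig^2
    mu <- matrix(0, N, n_samples)
    pos <- mu0 > 0 & is.finite(shape) & shape > 0
    mu[pos] <- stats::rgamma(sum(pos), shape = shape[pos],
                             scale = mu0[pos] / shape[pos])
    # degenerate dispersion (sigma_i = 0): gamma collapses to a point mass
    pt_mass <- mu0 > 0 & !pos
    mu[pt_mass] <- mu0[pt_mass]
    v <- matrix(stats::rpois(length(mu), mu), N, n_samples)
    rownames(v) <- names(feature_props)
    colnames(v) <- paste0("sample", seq_len(n_samples))
    v
  })
}
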