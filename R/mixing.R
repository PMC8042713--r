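# Mixture assembly M = S x W + noise and the scenario builders.

#' Construct a MixtureSet
#'
#' Bundles a simulated mixture with its dual ground truths and provenance.
#'
#' @param mixture an [expression_matrix()] (genes x samples).
#' @param truth_absolute [weight_matrix()] including any unknown row;
#'   columns sum to 1 over all components.
#' @param truth_relative [weight_matrix()] over known cell types only;
#'   columns sum to 1.
#' @param noise the [noise_spec()] used.
#' @param scenario_tag one of `"sim1_simModel"`, `"sim1_libSize"`, `"sim2"`,
#'   `"sim3"`, `"custom"`.
#' @param source_tag dataset provenance of the source profiles.
#' @param seed seed recorded for provenance.
#' @return an object of class `MixtureSet`.
#' @export
mixture_set <- function(mixture, truth_absolute, truth_relative, noise,
                        scenario_tag = "custom", source_tag = "synthetic",
                        seed = NA_integer_) {
  stopifnot(inherits(mixture, "ExpressionMatrix"),
            inherits(truth_absolute, "WeightMatrix"),
            inherits(truth_relative, "WeightMatrix"))
  if (ncol(mixture$values) != ncol(truth_absolute$values) ||
      ncol(mixture$values) != ncol(truth_relative$values))
    abort("mixture sample count must equal truth column count")
  structure(list(mixture = mixture, truth_absolute = truth_absolute,
                 truth_relative = truth_relative, noise = noise,
                 scenario_tag = scenario_tag, source_tag = source_tag,
                 seed = seed),
            class = "MixtureSet")
}

#' @export
print.MixtureSet <- function(x, ...) {
  cat(sprintf(
    "MixtureSet [%s] from %s: %d genes x %d samples (%s, p_t = %s)\n",
    x$scenario_tag, x$source_tag, nrow(x$mixture$values),
    ncol(x$mixture$values), x$noise$model, format(x$noise$p_t)))
  invisible(x)
}

#' Expected (noise-free) mixture S x W
#'
#' @param src a [source_profiles()] object supplying S.
#' @param w a [weight_matrix()]; its cell types must all exist in `src`.
#' @return numeric genes x samples matrix.
#' @export
mix_expected <- function(src, w) {
  stopifnot(inherits(src, "SourceProfiles"), inherits(w, "WeightMatrix"))
  missing <- setdiff(w$cell_types, src$cell_types)
  if (length(missing))
    abort("source profiles lack cell types: %s",
          paste(missing, collapse = ", "))
  src$mean_profiles[, w$cell_types, drop = FALSE] %*% w$values
}

#' Apply a noise model to an expected mixture
#'
#' `mixture_level` perturbs the expected mixture S x W per sample with the
#' chosen model; for the nb model the per-sample feature proportions are the
#' expected mixture column normalized to sum to 1.  `component_level` (nb
#' only) simulates an independent count realization per cellular component
#' and sums them weighted by W, so each component contributes its own
#' gamma-Poisson noise.  Output unit is `count` for nb, the source unit
#' otherwise.
#'
#' @param expected genes x samples expected mixture (from [mix_expected()]).
#' @param spec a [noise_spec()].
#' @param mode `"mixture_level"` or `"component_level"`.
#' @param w,src required for `component_level`: the weight matrix and the
#'   source profiles whose components are simulated.
#' @param unit unit label for normal/log-normal output (default `"count"`).
#' @param round_counts round component-level sums to integers (default
#'   `FALSE`; weighted sums of counts are real-valued).
#' @return an [expression_matrix()].
#' @export
apply_noise <- function(expected, spec,
                        mode = c("mixture_level", "component_level"),
                        w = NULL, src = NULL, unit = "count",
                        round_counts = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "NoiseSpec"))
  expected <- as.matrix(expected)
  if (spec$model != "nb") {
    if (mode == "component_level")
      abort("component_level noise is defined for the nb model only")
    out <- switch(spec$model,
                  normal = perturb_normal(expected, spec),
                  lognormal = perturb_lognormal(expected, spec))
    return(expression_matrix(out, unit = unit))
  }
  J <- ncol(expected)
  if (mode == "mixture_level") {
    v <- matrix(0L, nrow(expected), J, dimnames = dimnames(expected))
    for (j in seq_len(J)) {
      sp <- spec
      sp$seed <- if (is.null(spec$seed)) NULL else
        derive_seed(spec$seed, sprintf("nbmix/%d", j))
      sp$library_size <- if (length(spec$library_size) == 1L)
        spec$library_size else spec$library_size[j]
      r <- expected[, j] / sum(expected[, j])
      v[, j] <- simulate_nb_counts(r, sp, 1L)
    }
    colnames(v) <- paste0("sample", seq_len(J))
    return(expression_matrix(v, unit = "count"))
  }
  # component level: one noisy realization per component per sample
  if (is.null(w) || is.null(src))
    abort("component_level mode requires w and src")
  stopifnot(inherits(w, "WeightMatrix"), inherits(src, "SourceProfiles"))
  N <- nrow(src$mean_profiles)
  v <- matrix(0, N, J)
  for (k in seq_along(w$cell_types)) {
    ct <- w$cell_types[k]
    prof <- src$mean_profiles[, ct]
    r <- prof / sum(prof)
    sp <- spec
    sp$seed <- if (is.null(spec$seed)) NULL else
      derive_seed(spec$seed, sprintf("nbcomp/%s", ct))
    comp <- simulate_nb_counts(r, sp, J)
    v <- v + sweep(comp, 2, w$values[k, ], "*")
  }
  if (round_counts) v <- round(v)
  dimnames(v) <- list(rownames(src$mean_profiles),
                      paste0("sample", seq_len(J)))
  expression_matrix(v, unit = "count")
}

zero_spike_truths <- function(w) list(absolute = w, relative = w)

# wrap a weight matrix as its own dual ground truth (no unknown content)
make_mixture_set <- function(mixture, w, noise, scenario_tag, source_tag,
                             seed) {
  mixture_set(mixture, truth_absolute = w, truth_relative = w, noise = noise,
              scenario_tag = scenario_tag, source_tag = source_tag,
              seed = seed)
}

#' Scenario configuration for the simulation builders
#'
#' @param models noise models to run (subset of `"normal"`, `"lognormal"`,
#'   `"nb"`).
#' @param p_t_grid perturbation levels; `NULL` uses each model's own
#'   10-level grid ([pt_grid()]).
#' @param n_genes genes per synthetic source dataset.
#' @param n_source_datasets independent source datasets for the
#'   mixture-reference pairing design (3 in the replicated design).
#' @param J samples per mixture set (default 20).
#' @param K cellular components for Sim1 (default 3: T, B, monocytes).
#' @param component_grid component numbers for Sim2 (subset of 5:10).
#' @param regimes weight regimes for Sim2 (subset of `"orthog"`, `"real"`,
#'   `"dominant"`, `"uniform"`).
#' @param units quantification units to emit where the builder converts.
#' @param library_size nb library size (Sim1_simModel fixes 12e6).
#' @param sim2_p_t low nb noise level used by Sim2/Sim3 (default 0.1, the
#'   first level of the nb grid).
#' @param n_replicates purified replicates per cell type.
#' @param nb_mode `"component_level"` (default) or `"mixture_level"` nb
#'   mixing.
#' @return an object of class `Scenario`.
#' @export
scenario <- function(models = c("normal", "lognormal", "nb"),
                     p_t_grid = NULL, n_genes = 1000L,
                     n_source_datasets = 3L, J = 20L, K = 3L,
                     component_grid = 5:10,
                     regimes = c("orthog", "real"),
                     units = c("count", "countNorm", "cpm", "tpm"),
                     library_size = 12e6, sim2_p_t = 0.1,
                     n_replicates = 5L,
                     nb_mode = c("component_level", "mixture_level")) {
  models <- match.arg(models, several.ok = TRUE)
  regimes <- match.arg(regimes,
                       c("orthog", "real", "dominant", "uniform"),
                       several.ok = TRUE)
  units <- match.arg(units, c("count", "countNorm", "cpm", "tpm"),
                     several.ok = TRUE)
  nb_mode <- match.arg(nb_mode)
  stopifnot(all(component_grid %in% 5:10), is_count1(J), is_count1(n_genes))
  structure(list(models = models, p_t_grid = p_t_grid, n_genes = n_genes,
                 n_source_datasets = n_source_datasets, J = J, K = K,
                 component_grid = component_grid, regimes = regimes,
                 units = units, library_size = library_size,
                 sim2_p_t = sim2_p_t, n_replicates = n_replicates,
                 nb_mode = nb_mode),
            class = "Scenario")
}

#' Cell-type rosters for the component-number gradient
#'
#' Comp 5 is T, B, monocytes, neutrophils and NK cells; each step adds one
#' type (eosinophils, myeloid DC, CD34+ HSC), Comp 9 splits T into CD4/CD8,
#' and Comp 10 additionally splits B into naive/memory.
#'
#' @param K component number in 5:10.
#' @return character vector of K cell-type labels.
#' @export
component_roster <- function(K) {
  stopifnot(K %in% 5:10)
  switch(as.character(K),
    "5" = c("T", "B", "monocytes", "neutrophils", "NK"),
    "6" = c("T", "B", "monocytes", "neutrophils", "NK", "eosinophils"),
    "7" = c("T", "B", "monocytes", "neutrophils", "NK", "eosinophils",
            "myeloid_DC"),
    "8" = c("T", "B", "monocytes", "neutrophils", "NK", "eosinophils",
            "myeloid_DC", "CD34_HSC"),
    "9" = c("CD4_T", "CD8_T", "B", "monocytes", "neutrophils", "NK",
            "eosinophils", "myeloid_DC", "CD34_HSC"),
    "10" = c("CD4_T", "CD8_T", "naive_B", "memory_B", "monocytes",
             "neutrophils", "NK", "eosinophils", "myeloid_DC", "CD34_HSC"))
}

make_weights_for <- function(regime, K, J, cell_types, seed) {
  switch(regime,
         orthog = make_orthog(K, J, seed = seed, cell_types = cell_types),
         real = make_real(K, J, cell_types = cell_types, seed = seed),
         dominant = make_dominant(K, J, seed = seed,
                                  cell_types = cell_types),
         uniform = make_uniform(K, J, seed = seed, cell_types = cell_types))
}

nb_mixture <- function(src, w, spec, nb_mode) {
  expected <- mix_expected(src, w)
  apply_noise(expected, spec, mode = nb_mode, w = w, src = src)
}

#' Sim1 builder: noise structure across models and levels
#'
#' For every model x perturbation level, generates
#' `scenario$n_source_datasets` independent source datasets (shared marker
#' biology, dataset-level variation), simulates one mixture set and builds
#' one reference from each, and enumerates all mixture x reference
#' pairings — with 3 datasets, 9 replicated testing environments per level,
#' 6 of them with mixture and reference from different sources.  nb
#' simulations run at the fixed configured library size (12e6 by default).
#'
#' @param scen a [scenario()].
#' @param seed master seed.
#' @return list of environments, each a list with `mixture` (a
#'   [mixture_set()]), `reference`, `reference_tag`, `model`, `p_t` and
#'   `pair_id`; the weight regime is `"orthog"`.
#' @export
build_sim1 <- function(scen = scenario(), seed = 1L) {
  stopifnot(inherits(scen, "Scenario"))
  sources <- generate_source_datasets(
    scen$n_source_datasets, scen$n_genes, component_roster(5)[seq_len(scen$K)],
    n_replicates = scen$n_replicates,
    seed = derive_seed(seed, "sim1/sources"))
  refs <- lapply(sources, build_reference)
  out <- list()
  for (model in scen$models) {
    grid <- if (is.null(scen$p_t_grid)) pt_grid(model) else scen$p_t_grid
    for (p_t in grid) {
      mixtures <- lapply(seq_along(sources), function(d) {
        src <- sources[[d]]
        w_seed <- derive_seed(seed, sprintf("sim1/w/%d", d))
        w <- make_orthog(scen$K, scen$J, seed = w_seed,
                         cell_types = src$cell_types[seq_len(scen$K)])
        spec <- noise_spec(model, p_t = p_t,
                           library_size = scen$library_size,
                           seed = derive_seed(
                             seed, sprintf("sim1/%s/%s/%d", model, p_t, d)))
        mx <- if (model == "nb") nb_mixture(src, w, spec, scen$nb_mode)
              else expression_matrix(
                perturb_to(model, mix_expected(src, w), spec), unit = "count")
        make_mixture_set(mx, w, spec, "sim1_simModel", src$dataset_tag,
                         spec$seed)
      })
      for (d in seq_along(sources)) {
        for (r in seq_along(sources)) {
          out[[length(out) + 1L]] <- list(
            mixture = mixtures[[d]], reference = refs[[r]],
            reference_tag = sources[[r]]$dataset_tag, model = model,
            p_t = p_t, pair_id = sprintf("m%d_r%d", d, r))
        }
      }
    }
  }
  out
}

perturb_to <- function(model, expected, spec) {
  switch(model, normal = perturb_normal(expected, spec),
         lognormal = perturb_lognormal(expected, spec))
}

#' Sim1_libSize builder: two library-size groups
#'
#' nb mixtures whose first J/2 samples have 12 M reads and remaining J/2
#' have 24 M reads, emitted in the requested quantification units so that
#' library-size-sensitive behaviour of downstream methods can be probed.
#'
#' @param scen a [scenario()] (J must be even; 20 in the standard design).
#' @param seed master seed.
#' @param p_t_grid nb noise levels (default the nb grid).
#' @return list over (p_t, unit) of [mixture_set()] objects with
#'   `scenario_tag = "sim1_libSize"`; each carries the per-sample library
#'   sizes in `noise$library_size`.
#' @export
build_sim1_libsize <- function(scen = scenario(), seed = 1L,
                               p_t_grid = pt_grid("nb")) {
  stopifnot(inherits(scen, "Scenario"))
  if (scen$J %% 2L != 0L) abort("J must be even for the two-group design")
  src <- generate_source_profiles(
    scen$n_genes, component_roster(5)[seq_len(scen$K)],
    n_replicates = scen$n_replicates,
    seed = derive_seed(seed, "sim1ls/source"))
  L <- rep(c(12e6, 24e6), each = scen$J / 2L)
  out <- list()
  for (p_t in p_t_grid) {
    w <- make_orthog(scen$K, scen$J,
                     seed = derive_seed(seed, "sim1ls/w"),
                     cell_types = src$cell_types[seq_len(scen$K)])
    spec <- noise_spec("nb", p_t = p_t, library_size = L,
                       seed = derive_seed(seed, sprintf("sim1ls/%s", p_t)))
    counts <- nb_mixture(src, w, spec, scen$nb_mode)
    counts$gene_lengths <- src$gene_lengths
    for (unit in scen$units) {
      mx <- convert_units(counts, unit)
      out[[length(out) + 1L]] <- make_mixture_set(
        mx, w, spec, "sim1_libSize", src$dataset_tag, spec$seed)
    }
  }
  out
}

#' Sim2 builder: component-number gradient and weight regimes
#'
#' One nb mixture set per (K, regime) pair over the component gradient
#' (rosters from [component_roster()]), at a low noise level (the first
#' point of the nb grid by default).
#'
#' @param scen a [scenario()]; `component_grid` and `regimes` select the
#'   design.
#' @param seed master seed.
#' @return list of [mixture_set()] objects (tag `"sim2"`), each with the
#'   generating [source_profiles()] attached as `$source` and the regime in
#'   `$regime`.
#' @export
build_sim2 <- function(scen = scenario(), seed = 1L) {
  stopifnot(inherits(scen, "Scenario"))
  out <- list()
  for (K in scen$component_grid) {
    roster <- component_roster(K)
    src <- generate_source_profiles(
      scen$n_genes, roster, n_replicates = scen$n_replicates,
      seed = derive_seed(seed, sprintf("sim2/source/K%d", K)))
    for (regime in scen$regimes) {
      w <- make_weights_for(regime, K, scen$J, roster,
                            derive_seed(seed, sprintf("sim2/w/%s/K%d",
                                                      regime, K)))
      spec <- noise_spec("nb", p_t = scen$sim2_p_t,
                         library_size = scen$library_size,
                         seed = derive_seed(seed, sprintf("sim2/%s/K%d",
                                                          regime, K)))
      ms <- make_mixture_set(nb_mixture(src, w, spec, scen$nb_mode), w, spec,
                             "sim2", src$dataset_tag, spec$seed)
      ms$source <- src
      ms$regime <- regime
      ms$K <- K
      out[[length(out) + 1L]] <- ms
    }
  }
  out
}

#' Sim3 builder: tumor spike-ins and dual ground truths
#'
#' For each Sim2 mixture set and spike group, appends a tumor fraction to
#' the weight matrix, re-mixes in count space from the immune sources plus
#' the tumor profile, converts to the requested units, and attaches the two
#' ground truths: absolute (immune rows as-is, summing with the tumor row to
#' 1) and relative (immune rows renormalized to sum to 1).
#'
#' @param sim2_sets output of [build_sim2()] (with `$source` attached).
#' @param tumor_src [source_profiles()] holding the tumor component on the
#'   same genes (e.g. from [generate_tumor_profile()]).
#' @param spike_groups subset of `"small"`, `"large"`, `"mosaic"`.
#' @param scen a [scenario()]; supplies units, library size and nb mode.
#' @param seed master seed.
#' @param mode spike-in mode, see [spike_spec()].
#' @return list of [mixture_set()] objects with `scenario_tag = "sim3"`.
#' @export
build_sim3 <- function(sim2_sets, tumor_src,
                       spike_groups = c("small", "large", "mosaic"),
                       scen = scenario(), seed = 1L,
                       mode = "final_fraction") {
  stopifnot(inherits(tumor_src, "SourceProfiles"))
  tumor_label <- tumor_src$cell_types[1]
  out <- list()
  for (i in seq_along(sim2_sets)) {
    ms <- sim2_sets[[i]]
    src <- ms$source
    if (is.null(src)) abort("sim2 sets must carry their $source profiles")
    if (tumor_label %in% src$cell_types)
      abort("tumor source must be distinct from the immune cell types")
    full <- combine_sources(src, tumor_src)
    for (grp in spike_groups) {
      sp <- spike_spec(grp, tumor_label = tumor_label, mode = mode)
      w_seed <- derive_seed(seed, sprintf("sim3/%d/%s", i, grp))
      w_abs <- add_tumor_spikein(ms$truth_relative, sp, seed = w_seed)
      spec <- ms$noise
      spec$seed <- derive_seed(seed, sprintf("sim3/noise/%d/%s", i, grp))
      counts <- nb_mixture(full, w_abs, spec, scen$nb_mode)
      counts$gene_lengths <- src$gene_lengths
      for (unit in scen$units) {
        mx <- convert_units(counts, unit)
        set <- mixture_set(mx, truth_absolute = w_abs,
                           truth_relative = ms$truth_relative, noise = spec,
                           scenario_tag = "sim3",
                           source_tag = src$dataset_tag, seed = spec$seed)
        set$spike_group <- grp
        set$regime <- ms$regime
        set$K <- ms$K
        set$source <- full
        set$tumor_label <- tumor_label
        out[[length(out) + 1L]] <- set
      }
    }
  }
  out
}

#' Generate a synthetic tumor-line expression profile
#'
#' A single-cell-type source standing in for an unknown tumor component:
#' log-normal baseline with its own highly expressed gene set, so the tumor
#' transcriptome is distinct from every immune profile.
#'
#' @param n_genes number of genes (must match the immune sources).
#' @param label cell-type label (default `"HCT116_like"`, a synthetic
#'   colorectal-carcinoma-style line).
#' @param n_replicates purified replicates.
#' @param seed integer seed.
#' @return a [source_profiles()] object with one cell type.
#' @export
generate_tumor_profile <- function(n_genes, label = "HCT116_like",
                                   n_replicates = 5L, seed = 99L) {
  generate_source_profiles(n_genes, label, marker_frac = 0.05,
                           marker_fold = 50, n_replicates = n_replicates,
                           seed = seed)
}

# column-bind two SourceProfiles defined on the same genes
combine_sources <- function(a, b) {
  if (!identical(rownames(a$mean_profiles), rownames(b$mean_profiles)))
    abort("source profiles must share the same genes")
  out <- source_profiles(cbind(a$mean_profiles, b$mean_profiles),
                         c(a$replicates, b$replicates),
                         dataset_tag = paste(a$dataset_tag, b$dataset_tag,
                                             sep = "+"))
  out$gene_lengths <- a$gene_lengths
  out
}
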