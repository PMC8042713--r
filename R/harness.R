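# Orchestration: one seeded run tying simulate -> select genes ->
# deconvolve -> evaluate -> diagnose, with TSV outputs and a manifest.

#' Run configuration
#'
#' @param scenario_tag `"sim1_simModel"`, `"sim1_libSize"`, `"sim2"` or
#'   `"sim3"`.
#' @param scen a [scenario()] describing the simulation design.
#' @param seed master seed; every stage derives its own stream from it via
#'   [derive_seed()], so adding stages never shifts existing streams.
#' @param methods methods to run; currently `"builtin_nnls"` and/or named
#'   directories of external estimate TSVs.
#' @param scales evaluation scales, subset of `"relative"`, `"absolute"`.
#' @param out_dir output directory.
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(scenario_tag = c("sim1_simModel", "sim1_libSize",
                                        "sim2", "sim3"),
                       scen = scenario(), seed = 1L,
                       methods = "builtin_nnls",
                       scales = c("relative", "absolute"),
                       out_dir = tempfile("deconvbench_run_")) {
  scenario_tag <- match.arg(scenario_tag)
  structure(list(scenario_tag = scenario_tag, scen = scen,
                 seed = as.integer(seed), methods = methods,
                 scales = scales, out_dir = out_dir),
            class = "RunConfig")
}

write_weight_matrix <- function(w, path) {
  df <- data.frame(cell_type = rownames(w$values), w$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

eval_pair <- function(mixture_set, reference, markers, condition, scales) {
  est <- nnls_deconvolve(mixture_set$mixture, reference,
                         genes = unlist(markers))
  rows <- list()
  for (sc in scales) {
    truth <- if (sc == "absolute") mixture_set$truth_absolute else
      mixture_set$truth_relative
    tv <- truth$values
    tv <- tv[intersect(rownames(tv), rownames(est$values)), , drop = FALSE]
    if (!setequal(rownames(tv), rownames(est$values))) next
    rows[[sc]] <- evaluate_celltype(est, tv, scale = sc,
                                    condition = condition)
  }
  do.call(rbind, rows)
}

#' Run a full seeded benchmark
#'
#' Simulates the configured scenario, selects markers from each reference's
#' purified replicates, runs the built-in NNLS baseline, scores it on the
#' requested scales, and writes mixtures, truths, references, the
#' evaluation table and a JSON manifest into the run directory.  Re-running
#' with the same config reproduces identical tables.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `results` (evaluation data.frame),
#'   `summary`, `manifest` and `out_dir`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("mixtures", "truths", "references", "results"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  scen <- config$scen
  seed <- config$seed
  results <- list()
  n_env <- 0L

  emit <- function(ms, ref, markers, condition, tag) {
    n_env <<- n_env + 1L
    write_expression_matrix(ms$mixture,
                            file.path(config$out_dir, "mixtures",
                                      paste0(tag, ".tsv")))
    write_weight_matrix(ms$truth_absolute,
                        file.path(config$out_dir, "truths",
                                  paste0(tag, ".tsv")))
    if ("builtin_nnls" %in% config$methods)
      results[[length(results) + 1L]] <<-
        eval_pair(ms, ref, markers, condition, config$scales)
  }

  if (config$scenario_tag == "sim1_simModel") {
    envs <- build_sim1(scen, seed = seed)
    refs_written <- character()
    for (e in envs) {
      key <- e$reference_tag
      if (!key %in% refs_written) {
        write_expression_matrix(e$reference,
                                file.path(config$out_dir, "references",
                                          paste0(key, ".tsv")))
        refs_written <- c(refs_written, key)
      }
      cond <- list(model = e$model, p_t = e$p_t, pair = e$pair_id)
      tag <- sprintf("sim1_%s_p%s_%s", e$model, e$p_t, e$pair_id)
      emit(e$mixture, e$reference, NULL, cond, tag)
    }
  } else if (config$scenario_tag == "sim1_libSize") {
    sets <- build_sim1_libsize(scen, seed = seed)
    # reference from the same source profiles the builder used
    src <- generate_source_profiles(
      scen$n_genes, component_roster(5)[seq_len(scen$K)],
      n_replicates = scen$n_replicates,
      seed = derive_seed(seed, "sim1ls/source"))
    ref <- build_reference(src)
    for (i in seq_along(sets)) {
      ms <- sets[[i]]
      cond <- list(p_t = ms$noise$p_t, unit = ms$mixture$unit)
      emit(ms, ref, NULL, cond,
           sprintf("sim1ls_p%s_%s", ms$noise$p_t, ms$mixture$unit))
    }
  } else if (config$scenario_tag %in% c("sim2", "sim3")) {
    sets <- build_sim2(scen, seed = seed)
    if (config$scenario_tag == "sim3") {
      tumor <- generate_tumor_profile(scen$n_genes,
                                      seed = derive_seed(seed, "sim3/tumor"))
      sets <- build_sim3(sets, tumor, scen = scen, seed = seed)
    }
    for (i in seq_along(sets)) {
      ms <- sets[[i]]
      include <- ms$truth_relative$cell_types
      ref <- build_reference(ms$source, include = include)
      markers <- select_markers(
        ms$source$replicates[include])
      cond <- list(K = ms$K, regime = ms$regime,
                   spike = if (is.null(ms$spike_group)) "none" else
                     ms$spike_group,
                   unit = ms$mixture$unit)
      emit(ms, ref, markers, cond,
           sprintf("%s_K%d_%s_%d", config$scenario_tag, ms$K, ms$regime, i))
    }
  }

  results <- do.call(rbind, results)
  if (!is.null(results)) {
    utils::write.table(results,
                       file.path(config$out_dir, "results", "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- if (!is.null(results))
    summarize_results(results,
                      intersect(c("method", "model", "p_t", "K", "regime",
                                  "scale"), names(results))) else NULL
  manifest <- list(
    scenario = config$scenario_tag, seed = config$seed,
    n_environments = n_env,
    package_version = as.character(utils::packageVersion("deconvbench")),
    config_hash = derive_seed(config$seed,
                              paste(config$scenario_tag,
                                    paste(config$methods, collapse = ","))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, summary = summary, manifest = manifest,
                 out_dir = config$out_dir))
}
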