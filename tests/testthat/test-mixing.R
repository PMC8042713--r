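test_that("expected mixtures are exact linear combinations of source profiles", {
  src <- fixture_source(seed = 1, n_genes = 300)
  # single component at weight 1: mixture equals the profile
  w1 <- weight_matrix(matrix(c(1, 0, 0), 3, 2,
                             dimnames = list(src$cell_types, NULL)))
  expect_equal(mix_expected(src, w1)[, 1], src$mean_profiles[, "T"],
               ignore_attr = TRUE)
  # marker linearity: w_T = 0.3 scales T's marker contribution
  w <- weight_matrix(matrix(c(0.3, 0.4, 0.3), 3, 1,
                            dimnames = list(src$cell_types, NULL)))
  mk <- src$markers$T[1]
  manual <- sum(src$mean_profiles[mk, ] * c(0.3, 0.4, 0.3))
  expect_equal(mix_expected(src, w)[mk, 1], manual)
  # unknown cell type errors
  wbad <- weight_matrix(matrix(1, 1, 1, dimnames = list("X", NULL)))
  expect_error(mix_expected(src, wbad), "lack cell types")
})

test_that("apply_noise honours model/mode contracts", {
  src <- fixture_source(seed = 2, n_genes = 300)
  w <- make_uniform(3, 4, seed = 2, cell_types = src$cell_types)
  expected <- mix_expected(src, w)
  spec0 <- noise_spec("normal", p_t = 0)
  out <- apply_noise(expected, spec0, mode = "mixture_level")
  expect_equal(out$values, expected + 1, ignore_attr = TRUE)
  expect_error(apply_noise(expected, spec0, mode = "component_level",
                           w = w, src = src),
               "nb model only")

  # component_level with degenerate weights reproduces the single component
  wdeg <- weight_matrix(matrix(c(1, 0, 0), 3, 6,
                               dimnames = list(src$cell_types, NULL)))
  spec <- noise_spec("nb", p_t = 0.2, library_size = 1e6, seed = 3)
  mix <- apply_noise(mix_expected(src, wdeg), spec,
                     mode = "component_level", w = wdeg, src = src)
  r_T <- src$mean_profiles[, "T"] / sum(src$mean_profiles[, "T"])
  spec_T <- spec
  spec_T$seed <- derive_seed(3, "nbcomp/T")
  direct <- simulate_nb_counts(r_T, spec_T, 6)
  expect_equal(unname(mix$values), unname(direct))
})

test_that("nb mixtures recover the configured library size", {
  src <- fixture_source(seed = 4, n_genes = 2000)
  w <- make_orthog(3, 10, seed = 4, cell_types = src$cell_types)
  spec <- noise_spec("nb", p_t = 0.1, library_size = 2e6, seed = 5)
  for (mode in c("mixture_level", "component_level")) {
    m <- apply_noise(mix_expected(src, w), spec, mode = mode,
                     w = w, src = src)
    expect_equal(mean(colSums(m$values)) / 2e6, 1, tolerance = 0.01,
                 label = mode)
  }
})

test_that("sim1 enumerates the replicated mixture-reference pairing design", {
  scen <- scenario(models = "nb", n_genes = 300, J = 6, K = 3)
  envs <- build_sim1(scen, seed = 1)
  expect_length(envs, 10 * 9)   # 10 nb levels x (3 x 3) pairings
  lvl <- Filter(function(e) e$p_t == 0.1, envs)
  expect_length(lvl, 9)
  cross <- vapply(lvl, function(e)
    !identical(e$mixture$source_tag, e$reference_tag), logical(1))
  expect_equal(sum(cross), 6)

  solo <- build_sim1(scenario(models = "nb", p_t_grid = 0.1,
                              n_source_datasets = 1, n_genes = 300,
                              J = 6, K = 3), seed = 1)
  expect_length(solo, 1)
  expect_identical(solo[[1]]$mixture$source_tag, solo[[1]]$reference_tag)
})

test_that("sim1_libSize produces the 12M/24M two-group design in every unit", {
  scen <- scenario(models = "nb", n_genes = 2000, J = 20, K = 3,
                   units = c("count", "cpm"))
  sets <- build_sim1_libsize(scen, seed = 2, p_t_grid = 0.1)
  expect_length(sets, 2)
  units <- vapply(sets, function(s) s$mixture$unit, character(1))
  counts <- sets[[which(units == "count")]]
  lib <- colSums(counts$mixture$values)
  expect_equal(mean(lib[1:10]) / 12e6, 1, tolerance = 0.01)
  expect_equal(mean(lib[11:20]) / 24e6, 1, tolerance = 0.01)
  expect_equal(mean(lib[11:20]) / mean(lib[1:10]), 2, tolerance = 0.02)
  # cpm conversion removes the split
  cpm <- sets[[which(units == "cpm")]]
  expect_equal(unname(colSums(cpm$mixture$values)), rep(1e6, 20))
  expect_error(build_sim1_libsize(scenario(J = 7), seed = 1), "even")
})

test_that("sim2 covers the (K, regime) grid with the component rosters", {
  expect_identical(component_roster(5),
                   c("T", "B", "monocytes", "neutrophils", "NK"))
  expect_true(all(c("CD4_T", "CD8_T") %in% component_roster(9)))
  expect_true(all(c("naive_B", "memory_B") %in% component_roster(10)))
  expect_length(component_roster(10), 10)

  scen <- scenario(models = "nb", n_genes = 1000, J = 6,
                   component_grid = c(5, 6), regimes = c("orthog", "real"))
  sets <- build_sim2(scen, seed = 3)
  expect_length(sets, 4)
  ks <- vapply(sets, function(s) s$K, numeric(1))
  regs <- vapply(sets, function(s) s$regime, character(1))
  expect_setequal(paste(ks, regs),
                  c("5 orthog", "5 real", "6 orthog", "6 real"))
  expect_identical(sets[[1]]$truth_relative$cell_types, component_roster(5))
})

test_that("sim3 attaches consistent dual ground truths", {
  scen <- scenario(models = "nb", n_genes = 1000, J = 5,
                   component_grid = 5, regimes = "orthog",
                   units = "count")
  sim2 <- build_sim2(scen, seed = 4)
  tumor <- generate_tumor_profile(1000, seed = 40)
  sim3 <- build_sim3(sim2, tumor, scen = scen, seed = 4)
  expect_length(sim3, 3)   # 1 input set x 3 spike groups
  for (ms in sim3) {
    t_j <- ms$truth_absolute$values[ms$tumor_label, ]
    imm <- ms$truth_absolute$values[ms$truth_relative$cell_types, ]
    # absolute immune rows = relative rows x (1 - t_j)
    expect_equal(imm, sweep(ms$truth_relative$values, 2, 1 - t_j, "*"),
                 tolerance = 1e-9)
    # renormalizing absolute over known types reproduces relative
    expect_equal(sweep(imm, 2, colSums(imm), "/"), ms$truth_relative$values,
                 tolerance = 1e-9)
  }
})

test_that("baseline estimates are unit-invariant under fixed library size", {
  src <- fixture_source(seed = 5, n_genes = 1500)
  w <- make_orthog(3, 8, seed = 5, cell_types = src$cell_types)
  spec <- noise_spec("nb", p_t = 0.1, library_size = 1e6, seed = 6)
  counts <- apply_noise(mix_expected(src, w), spec,
                        mode = "component_level", w = w, src = src)
  counts$gene_lengths <- src$gene_lengths
  ref <- build_reference(src)
  est_count <- nnls_deconvolve(counts, ref)
  est_cpm <- nnls_deconvolve(convert_units(counts, "cpm"), ref)
  expect_equal(est_count$values, est_cpm$values, tolerance = 1e-6)
})
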