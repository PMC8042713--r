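test_that("synthetic source profiles embed exact-fold markers and are reproducible", {
  src1 <- generate_source_profiles(1000, c("A", "B", "C"), marker_frac = 0.02,
                                   marker_fold = 50, seed = 1)
  src2 <- generate_source_profiles(1000, c("A", "B", "C"), marker_frac = 0.02,
                                   marker_fold = 50, seed = 1)
  expect_identical(src1$mean_profiles, src2$mean_profiles)
  expect_identical(src1$replicates$A$values, src2$replicates$A$values)

  # each type owns floor(0.02 * 1000 / 3) = 6 disjoint markers at ratio 50
  expect_equal(unname(lengths(src1$markers)), rep(6L, 3))
  expect_length(unique(unlist(src1$markers)), 18L)
  for (ct in names(src1$markers)) {
    mk <- src1$markers[[ct]]
    others <- setdiff(colnames(src1$mean_profiles), ct)
    for (ot in others)
      expect_equal(src1$mean_profiles[mk, ct] / src1$mean_profiles[mk, ot],
                   rep(50, length(mk)), ignore_attr = TRUE)
  }
})

test_that("marker budget and size preconditions are enforced", {
  expect_error(generate_source_profiles(20, c("A", "B", "C"),
                                        marker_frac = 0.01, seed = 1),
               "at least 10 per cell type")
  expect_error(generate_source_profiles(100, c("A", "B", "C"),
                                        marker_frac = 0.01, seed = 1),
               "marker budget too small")
})

test_that("low-abundance filtering uses strict > in at least min_samples samples", {
  v <- rbind(keep  = c(11, 11, 11, 11, 11, 0),
             drop  = c(11, 11, 11, 11, 0, 0),
             edge  = c(10, 10, 10, 10, 10, 10),  # never exceeds 10
             zeros = c(0, 0, 0, 0, 0, 0))
  m <- expression_matrix(v, unit = "count")
  f <- filter_low_abundance(m, min_samples = 5, min_expr = 10)
  expect_identical(rownames(f$values), "keep")
  expect_identical(colnames(f$values), colnames(m$values))

  # 4-sample matrix, threshold (4, 10): all entries 11 are retained
  m4 <- expression_matrix(matrix(11, 3, 4), unit = "count")
  expect_equal(nrow(filter_low_abundance(m4, min_samples = 4)$values), 3L)
  expect_error(filter_low_abundance(m4, min_samples = 5), "exceeds")
})

test_that("filtering is monotone in both thresholds", {
  set.seed(42)
  m <- expression_matrix(matrix(rpois(600, 8), 100, 6), unit = "count")
  base <- rownames(filter_low_abundance(m, 3, 5)$values)
  for (args in list(c(3, 8), c(5, 5), c(5, 8))) {
    sub <- rownames(filter_low_abundance(m, args[1], args[2])$values)
    expect_true(all(sub %in% base))
  }
})

test_that("unit conversions match the printed formulas and preserve mass", {
  m <- fixture_counts()
  cpm <- convert_units(m, "cpm")
  expect_equal(cpm$values[, "s1"], c(g1 = 1e5, g2 = 3e5, g3 = 6e5))
  expect_equal(unname(colSums(cpm$values)), c(1e6, 1e6))

  cn <- convert_units(m, "countNorm")
  # L_Median = median(1000, 2000) = 1500
  expect_equal(unname(colSums(cn$values)), c(1500, 1500))
  expect_equal(cn$values[, "s1"], c(g1 = 150, g2 = 450, g3 = 900))

  # equal gene lengths: tpm equals cpm for every gene
  tpm <- convert_units(m, "tpm")
  expect_equal(tpm$values, cpm$values, tolerance = 1e-12)
  expect_equal(unname(colSums(tpm$values)), c(1e6, 1e6))

  # per-sample gene proportions unchanged by any library-size normalization
  props <- function(x) sweep(x$values, 2, colSums(x$values), "/")
  expect_equal(props(cpm), props(m))
  expect_equal(props(cn), props(m))
})

test_that("unit conversion guards its preconditions", {
  m <- fixture_counts()
  m$gene_lengths <- NULL
  expect_error(convert_units(m, "tpm"), "gene_lengths")
  zero <- expression_matrix(cbind(c(1, 1), c(0, 0)), unit = "count")
  expect_error(convert_units(zero, "cpm"), "zero library")
  expect_error(convert_units(convert_units(fixture_counts(), "cpm"),
                             "countNorm"),
               "count unit")
})

test_that("references are replicate means restricted to included types", {
  src <- fixture_source(seed = 3, n_genes = 300)
  ref <- build_reference(src, include = c("T", "B"))
  expect_identical(colnames(ref$values), c("T", "B"))
  expect_equal(ref$values[, "T"], rowMeans(src$replicates$T$values))
  expect_false("mono" %in% colnames(ref$values))

  one <- build_reference(src, include = "mono")
  expect_equal(one$values[, 1], rowMeans(src$replicates$mono$values))
  expect_error(build_reference(src, include = character(0)), "at least one")
  expect_error(build_reference(src, include = "tumor"), "unknown cell types")
})

test_that("expression matrices round-trip through TSV with unit metadata", {
  m <- fixture_counts()
  path <- file.path(withr::local_tempdir(), "m.tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_equal(back$values, m$values)
  expect_identical(back$unit, "count")
  expect_equal(back$gene_lengths, m$gene_lengths)
})

test_that("ingestion rejects malformed matrices and dedups gene ids", {
  expect_error(expression_matrix(matrix(c(-1, 1), 2, 1)), "non-negative")
  expect_error(expression_matrix(matrix(c(NA, 1), 2, 1)), "missing")
  v <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"), NULL))
  expect_equal(nrow(expression_matrix(v)$values), 1L)
})
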