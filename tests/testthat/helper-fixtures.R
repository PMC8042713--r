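# Small fixtures shared across tests; everything is generated in code.

fixture_source <- function(seed = 1L, n_genes = 600L,
                           cell_types = c("T", "B", "mono")) {
  generate_source_profiles(n_genes, cell_types, marker_frac = 0.02,
                           marker_fold = 50, n_replicates = 5L, seed = seed)
}

# tiny count matrix with known structure
fixture_counts <- function() {
  v <- matrix(c(100, 300, 600,
                200, 600, 1200), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expression_matrix(v, unit = "count",
                    gene_lengths = c(g1 = 1, g2 = 1, g3 = 1))
}
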