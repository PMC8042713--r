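test_that("every weight generator returns columns summing to 1 within 1e-9", {
  gens <- list(
    make_orthog(4, 10, n_candidates = 50, seed = 1),
    make_real(5, 8, cell_types = c("neutrophils", "T", "B", "NK",
                                   "monocytes"), seed = 2),
    make_dominant(5, 10, seed = 3),
    make_uniform(5, 10, seed = 4))
  for (w in gens) {
    expect_true(all(abs(colSums(w$values) - 1) < 1e-9), label = w$regime)
    expect_true(all(w$values >= 0 & w$values <= 1), label = w$regime)
  }
})

test_that("make_orthog attains the minimum condition number over its candidates", {
  K <- 10; J <- 20; n <- 1000; seed <- 42
  w <- make_orthog(K, J, n_candidates = n, seed = seed)
  # brute-force rescan: regenerate the same seeded candidate stream
  kappas <- numeric(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    cand <- matrix(runif(K * J), K, J)
    cand <- sweep(cand, 2, colSums(cand), "/")
    kappas[i] <- condition_number(cand)
  }
  expect_equal(w$condition_number, min(kappas), tolerance = 1e-12)
  expect_identical(w$condition_number, condition_number(w$values))
})

test_that("make_orthog degenerate and error cases", {
  w1 <- make_orthog(1, 5, n_candidates = 10, seed = 1)
  expect_equal(unname(w1$values), matrix(1, 1, 5))
  expect_equal(w1$condition_number, 1)
  expect_error(make_orthog(5, 3, seed = 1), "at least K")
})

test_that("make_real keeps every entry in its band after rescaling", {
  rng <- real_blood_ranges()
  cts <- c("neutrophils", "T", "B", "NK", "monocytes")
  w <- make_real(5, 20, cell_types = cts, seed = 7)
  lo <- rng$min[match(cts, rng$cell_type)]
  hi <- rng$max[match(cts, rng$cell_type)]
  expect_true(all(w$values >= lo - 1e-9 & w$values <= hi + 1e-9))
  expect_true(all(abs(colSums(w$values) - 1) < 1e-9))

  # degenerate ranges give a deterministic column
  deg <- data.frame(cell_type = c("A", "B"), min = c(0.4, 0.6),
                    max = c(0.4, 0.6))
  wd <- make_real(2, 3, ranges = deg, seed = 1)
  expect_equal(unname(wd$values), matrix(c(0.4, 0.6), 2, 3))

  # infeasible ranges error out
  bad <- data.frame(cell_type = c("A", "B"), min = c(0.8, 0.8),
                    max = c(0.9, 0.9))
  expect_error(make_real(2, 3, ranges = bad, seed = 1), "cannot sum to 1")
})

test_that("dominant regime keeps the major component strictly above the minors", {
  w <- make_dominant(5, 25, major_type = "T",
                     cell_types = c("T", "B", "NK", "mono", "neut"), seed = 5)
  for (j in seq_len(25))
    expect_true(w$values["T", j] > max(w$values[-1, j]))
  expect_true(all(w$values["T", ] > 0.85))
  expect_error(make_dominant(1, 5, seed = 1), "at least 2")
})

test_that("uniform regime bounds the per-column max/min ratio", {
  K <- 5
  w <- make_uniform(K, 30, seed = 6)
  bound <- (1 / K + 0.04) / (1 / K)
  ratios <- apply(w$values, 2, function(col) max(col) / min(col))
  expect_true(all(ratios <= bound + 1e-12))
})

test_that("regime conditioning is ordered orthog < uniform < dominant", {
  mean_kappa <- function(fun) {
    mean(vapply(1:5, function(s) fun(s)$condition_number, numeric(1)))
  }
  k_orth <- mean_kappa(function(s) make_orthog(5, 20, seed = s))
  k_unif <- mean_kappa(function(s) make_uniform(5, 20, seed = s))
  k_dom <- mean_kappa(function(s) make_dominant(5, 20, seed = s))
  expect_lt(k_orth, k_unif)
  expect_lt(k_unif, k_dom)
})

test_that("tumor spike-ins hit their bands and preserve relative proportions", {
  w <- make_uniform(3, 12, seed = 8, cell_types = c("T", "B", "mono"))
  for (grp in c("small", "large", "mosaic")) {
    sp <- spike_spec(grp)
    ws <- add_tumor_spikein(w, sp, seed = 9)
    t_j <- ws$values["HCT116", ]
    expect_true(all(t_j >= sp$range[1] & t_j <= sp$range[2]), label = grp)
    expect_true(all(abs(colSums(ws$values) - 1) < 1e-9))
    # relative immune proportions unchanged
    rel <- sweep(ws$values[w$cell_types, ], 2,
                 colSums(ws$values[w$cell_types, ]), "/")
    expect_equal(rel, w$values, tolerance = 1e-12)
  }
})

test_that("spike-in arithmetic matches both mode conventions", {
  w <- weight_matrix(matrix(0.5, 2, 1, dimnames = list(c("A", "B"), "s1")))
  # final_fraction: immune scaled by 1 - t
  sp_ff <- spike_spec("small", range = c(0.5, 0.5 + 1e-9),
                      mode = "final_fraction")
  expect_equal(unname(add_tumor_spikein(w, sp_ff, 1)$values[, 1]),
               c(0.25, 0.25, 0.5), tolerance = 1e-6)
  # append_rescale with t = 1: divide by 1 + t
  sp_ar <- spike_spec("mosaic", range = c(1 - 1e-12, 1),
                      mode = "append_rescale")
  expect_equal(unname(add_tumor_spikein(w, sp_ar, 1)$values[, 1]),
               c(0.25, 0.25, 0.5), tolerance = 1e-6)
  # none: zero tumor row, identity otherwise
  ws0 <- add_tumor_spikein(w, spike_spec("none"), 1)
  expect_equal(unname(ws0$values[3, ]), 0)
  expect_equal(ws0$values[1:2, , drop = FALSE], w$values,
               ignore_attr = TRUE)
  expect_error(add_tumor_spikein(ws0, spike_spec("small"), 1),
               "already present")
})
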