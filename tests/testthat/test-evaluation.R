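test_that("pearson_r handles perfect, affine and degenerate inputs", {
  expect_equal(pearson_r(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6)), 1)
  expect_equal(pearson_r(c(0.2, 0.4, 0.6), c(0.3, 0.5, 0.7)), 1)
  expect_true(is.na(pearson_r(c(0.2, 0.4, 0.6), c(0.5, 0.5, 0.5))))
  expect_error(pearson_r(1:3, 1:4), "same length")
  expect_error(pearson_r(1, 2), "at least 2")
})

test_that("mean absolute deviance is exact, symmetric and bounded", {
  expect_equal(mean_abs_dev(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(mean_abs_dev(c(0.2, 0.4), c(0.3, 0.5)), 0.1)
  expect_equal(mean_abs_dev(c(0, 1), c(1, 0)), 1)
  x <- runif(10); y <- runif(10)
  expect_equal(mean_abs_dev(x, y), mean_abs_dev(y, x))
})

test_that("mAD detects a constant offset that r cannot see", {
  truth <- matrix(c(0.2, 0.8, 0.4, 0.6, 0.3, 0.7), 2, 3,
                  dimnames = list(c("A", "B"), NULL))
  shift <- 0.05
  est <- proportion_estimate(truth + shift, "shifted", "unnormalized")
  ev <- evaluate_celltype(est, truth)
  per_ct <- ev[ev$cell_type != "all", ]
  expect_equal(per_ct$mad, rep(shift, 2))
  expect_equal(per_ct$r, rep(1, 2))
})

test_that("NA estimates and zero-variance correlations get the maximal penalty", {
  truth <- matrix(c(0.3, 0.7, 0.5, 0.5, 0.2, 0.8), 2, 3,
                  dimnames = list(c("A", "B"), NULL))
  est_na <- matrix(c(NA, 0.7, NA, 0.5, NA, 0.8), 2, 3,
                   dimnames = list(c("A", "B"), NULL))
  ev <- evaluate_celltype(proportion_estimate(est_na, "m", "unnormalized"),
                          truth)
  expect_equal(ev$r[ev$cell_type == "A"], -1)
  expect_equal(ev$mad[ev$cell_type == "A"], 1)

  # all-zero estimate: r undefined -> -1; mAD = mean truth
  est0 <- matrix(c(0, 1, 0, 1, 0, 1), 2, 3,
                 dimnames = list(c("A", "B"), NULL))
  ev0 <- evaluate_celltype(proportion_estimate(est0, "m", "unnormalized"),
                           truth)
  expect_equal(ev0$r[ev0$cell_type == "A"], -1)
  expect_equal(ev0$mad[ev0$cell_type == "A"], mean(truth["A", ]))

  # perfect estimate: r = 1, mAD = 0 everywhere, metrics at their bounds
  evp <- evaluate_celltype(proportion_estimate(truth, "m", "unnormalized"),
                           truth)
  expect_equal(evp$r, rep(1, 3))
  expect_equal(evp$mad, rep(0, 3))
})

test_that("the all row is the unweighted mean over cell types", {
  truth <- matrix(c(0.3, 0.7, 0.5, 0.5, 0.2, 0.8), 2, 3,
                  dimnames = list(c("A", "B"), NULL))
  est <- matrix(c(NA, 0.7, NA, 0.5, NA, 0.8), 2, 3,
                dimnames = list(c("A", "B"), NULL))
  ev <- evaluate_celltype(proportion_estimate(est, "m", "unnormalized"),
                          truth)
  per_ct <- ev[ev$cell_type != "all", ]
  expect_equal(ev$r[ev$cell_type == "all"], mean(per_ct$r))
  expect_equal(ev$mad[ev$cell_type == "all"], mean(per_ct$mad))
})

test_that("dual scales coincide at zero unknown content and split with t", {
  w <- make_uniform(3, 6, seed = 51, cell_types = c("T", "B", "mono"))
  ws0 <- add_tumor_spikein(w, spike_spec("none"), seed = 1)
  gt0 <- ground_truth_scales(ws0)
  expect_equal(gt0$absolute, gt0$relative, tolerance = 1e-12)
  expect_equal(gt0$relative, w$values, tolerance = 1e-12)

  ws <- add_tumor_spikein(w, spike_spec("small"), seed = 2)
  gt <- ground_truth_scales(ws)
  t_j <- ws$values["HCT116", ]
  expect_equal(unname(colSums(gt$absolute)), unname(1 - t_j))
  expect_equal(unname(colSums(gt$relative)), rep(1, 6))
  expect_equal(gt$absolute, sweep(gt$relative, 2, 1 - t_j, "*"),
               tolerance = 1e-12)
  # column example: (0.3, 0.2, tumor 0.5) -> abs (0.3, 0.2), rel (0.6, 0.4)
  wt <- weight_matrix(matrix(c(0.3, 0.2, 0.5), 3, 1,
                             dimnames = list(c("A", "B", "tum"), NULL)))
  gt1 <- ground_truth_scales(wt, unknown_label = "tum")
  expect_equal(unname(gt1$absolute[, 1]), c(0.3, 0.2))
  expect_equal(unname(gt1$relative[, 1]), c(0.6, 0.4))
  expect_error(ground_truth_scales(w), "not found")
})

test_that("summaries average within groups and keep penalties in the mean", {
  res <- data.frame(method = c("m1", "m1", "m2", "m2"),
                    model = c("nb", "nb", "nb", "nb"),
                    r = c(0.8, 0.6, -1, 1), mad = c(0.1, 0.3, 1, 0))
  s <- summarize_results(res, over = "method")
  expect_equal(s$r[s$method == "m1"], 0.7)
  expect_equal(s$r[s$method == "m2"], 0)   # the -1 penalty is averaged in
  expect_equal(nrow(summarize_results(res, over = character(0))), 1L)
  expect_error(summarize_results(res, over = "nope"), "not present")
})

test_that("method ranking follows metric direction with average ties", {
  s <- data.frame(method = c("a", "b", "c"), cond = "x",
                  r = c(0.9, 0.5, 0.5), mad = c(0.01, 0.2, 0.2))
  rr <- rank_methods(s, "r")
  expect_equal(rr$rank, c(1, 2.5, 2.5))
  rm_ <- rank_methods(s, "mad")
  expect_equal(rm_$rank, c(1, 2.5, 2.5))
  s2 <- data.frame(method = c("a", "b"), r = c(0.5, 0.5),
                   mad = c(0.3, 0.3))
  expect_equal(rank_methods(s2, "r")$rank, c(1.5, 1.5))
})
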