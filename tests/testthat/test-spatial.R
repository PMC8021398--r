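test_that("reference TSVs round trip and reject malformed input", {
  dir <- withr::local_tempdir()
  ref <- simulate_reference(disc_sim_config())
  write_reference(ref, file.path(dir, "pos.tsv"), file.path(dir, "pat.tsv"))
  rt <- load_reference(file.path(dir, "pos.tsv"), file.path(dir, "pat.tsv"))
  expect_identical(rt$patterns, ref$patterns)
  expect_equal(rt$positions$id, ref$positions$id)

  bad <- ref$patterns; bad[1, 1] <- 2
  expect_error(flat_reference(bad[, 1:4]), "binary")
  pos2 <- ref$positions
  pat2 <- ref$patterns[, -1, drop = FALSE]
  expect_error(layered_reference(pos2, pat2), ref$positions$id[1])
  pos3 <- ref$positions; pos3$id[2] <- pos3$id[1]
  expect_error(layered_reference(pos3, ref$patterns), "duplicate")
})

test_that("cell binarization matches the nearest-rank quantile rule", {
  # f = 0.25 -> threshold is the 3rd order statistic of 4 values
  pat <- matrix(c(1, 0, 0, 0), 1, 4, dimnames = list("g1", NULL))
  ref <- flat_reference(pat)
  nm <- toy_norm(matrix(c(0, 0, 1, 4), 1), genes = "g1")
  b <- binarize_cells(nm, ref, "DP")
  expect_equal(unname(b[, "g1"]), c(0L, 0L, 0L, 1L))
  # f = 1: threshold is the minimum; cells above the minimum are positive
  ref1 <- flat_reference(matrix(1, 1, 4, dimnames = list("g1", NULL)))
  b1 <- binarize_cells(nm, ref1, "DP")
  expect_equal(unname(b1[, "g1"]), c(0L, 0L, 1L, 1L))
  # constant gene -> all zero
  nmc <- toy_norm(matrix(2, 1, 4), genes = "g1")
  expect_true(all(binarize_cells(nmc, ref, "DP") == 0))
  expect_error(binarize_cells(toy_norm(matrix(1, 1, 4), genes = "other"),
                              ref, "DP"), "missing")
})

test_that("binarized positive fractions track the reference fractions", {
  set.seed(44)
  n <- 400
  f <- c(0.1, 0.25, 0.5, 0.8)
  pat <- t(vapply(f, function(fi) as.integer(seq_len(20) <= 20 * fi),
                  integer(20)))
  rownames(pat) <- sprintf("g%d", 1:4)
  ref <- flat_reference(pat)
  nm <- toy_norm(matrix(runif(4 * n), 4), genes = sprintf("g%d", 1:4))
  b <- binarize_cells(nm, ref, "DP")
  expect_true(all(abs(colMeans(b) - f) <= 1 / n + 1e-9))
})

test_that("MCC scoring matches the contingency-table oracle", {
  v <- c(1, 1, 0, 0, 1)
  pat <- cbind(v, 1 - v, c(1, 1, 1, 0, 0))
  rownames(pat) <- sprintf("g%d", 1:5)
  ref <- flat_reference(pat)
  cellb <- matrix(v, 1, dimnames = list("c1", sprintf("g%d", 1:5)))
  s <- mcc_scores(cellb, ref, "DP")
  expect_equal(unname(s[1, 1]), 1.0)
  expect_equal(unname(s[1, 2]), -1.0)
  # TP=2, FP=1, FN=1, TN=3 -> 5/12
  a <- c(1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 0, 1, 0, 0, 0)
  ref2 <- flat_reference(matrix(b, ncol = 1,
                                dimnames = list(sprintf("g%d", 1:7), NULL)))
  s2 <- mcc_scores(matrix(a, 1, dimnames = list("c", sprintf("g%d", 1:7))),
                   ref2, "DP")
  expect_equal(unname(s2[1, 1]), 5 / 12, tolerance = 1e-12)
  # degenerate: all-ones cell vector -> zero denominator -> 0
  s3 <- mcc_scores(matrix(1, 1, 7, dimnames = list("c", sprintf("g%d", 1:7))),
                   ref2, "DP")
  expect_equal(unname(s3[1, 1]), 0)
})

test_that("softmax weights match closed forms and their limits", {
  s <- matrix(c(1, 0), 1, 2, dimnames = list("c", c("p1", "p2")))
  w <- mapping_weights(s, tau = 0.1)
  expect_equal(unname(w[1, ]), c(1 / (1 + exp(-10)), exp(-10) / (1 + exp(-10))),
               tolerance = 1e-12)
  expect_equal(rowSums(w), c(c = 1), tolerance = 1e-9)
  su <- matrix(0.3, 2, 5)
  expect_true(all(abs(mapping_weights(su) - 0.2) < 1e-12))
  expect_true(all(abs(mapping_weights(s, tau = 1e3)[1, ] - 0.5) < 1e-3))
  expect_gt(mapping_weights(s, tau = 1e-3)[1, 1], 1 - 1e-12)
  expect_error(mapping_weights(matrix(NaN, 1, 1)), "finite")
})

test_that("virtual in situ is a convex combination of cell values", {
  set.seed(51)
  w <- mapping_weights(matrix(rnorm(20 * 6), 20, 6,
                              dimnames = list(sprintf("c%02d", 1:20),
                                              sprintf("p%d", 1:6))))
  nm <- toy_norm(matrix(rexp(20), 1), genes = "gX",
                 cells = sprintf("c%02d", 1:20))
  v <- virtual_insitu(w, nm, "gX")
  x <- as.numeric(nm$values["gX", ])
  expect_true(all(v >= min(x) - 1e-12 & v <= max(x) + 1e-12))
  # constant gene -> constant prediction
  nmc <- toy_norm(matrix(3, 1, 20), genes = "gX",
                  cells = sprintf("c%02d", 1:20))
  expect_true(all(abs(virtual_insitu(w, nmc, "gX") - 3) < 1e-12))
  # a unit weight row reproduces that cell's value
  w1 <- matrix(0, 1, 3, dimnames = list("c01", c("p1", "p2", "p3")))
  w1[1, 2] <- 1
  expect_equal(unname(virtual_insitu(w1, nm, "gX")["p2"]), x[1])
  expect_error(virtual_insitu(w, nm, "missing"), "absent")
})

test_that("layer mapping keeps weight mass inside each cell's layer", {
  b <- simulate_disc(disc_sim_config(n_cells_per_batch = 150,
                                     doublet_rate = 0, seed = 55))
  tr <- b$truth
  nm <- normalize_total_log(subset_cells(b$counts, tr$cell_id))
  res <- map_layer(nm, b$reference, tr$layer)
  amp_cols <- b$reference$positions$layer == "AMP"
  amp_cells <- tr$layer == "AMP"
  expect_true(all(res$weights[amp_cells, !amp_cols] == 0))
  expect_true(all(res$weights[!amp_cells, amp_cols] == 0))
  expect_equal(unname(rowSums(res$weights)), rep(1, nrow(tr)),
               tolerance = 1e-9)
  expect_error(map_layer(nm, b$reference, rep(NA, nrow(tr))), "layer label")
})

test_that("noiseless pattern cells map to their true positions", {
  set.seed(61)
  p <- 60; g <- 20
  pat <- matrix(rbinom(g * p, 1, 0.5), g, p,
                dimnames = list(sprintf("lm%02d", 1:g), NULL))
  pat <- pat[, !duplicated(t(pat)), drop = FALSE]
  ref <- flat_reference(pat)
  truth_pos <- sample(ncol(pat), 200, replace = TRUE)
  cellb <- t(pat[, truth_pos])
  rownames(cellb) <- sprintf("c%03d", seq_along(truth_pos))
  s <- mcc_scores(cellb, ref, "DP")
  expect_equal(unname(apply(s, 1, which.max)), truth_pos)
  expect_true(all(s[cbind(seq_along(truth_pos), truth_pos)] == 1))
})

test_that("cluster localization concentrates planted programs spatially", {
  b <- simulate_disc(disc_sim_config(n_cells_per_batch = 400,
                                     doublet_rate = 0, seed = 65))
  tr <- b$truth
  epi <- tr$layer == "epithelium"
  nm <- normalize_total_log(subset_cells(b$counts, tr$cell_id[epi]))
  res <- map_layer(nm, b$reference, rep("epithelium", sum(epi)))
  loc <- cluster_localization(res, tr$domain[epi])
  expect_equal(unname(rowSums(loc)), rep(1, nrow(loc)), tolerance = 1e-9)
  # notum region of the epithelial map: disc-proper notum positions plus
  # the peripodial outline overlying them (same proximodistal span)
  pos <- b$reference$positions
  notum_cols <- pos$layer != "AMP" & pos$x <= 0.35
  expect_gte(sum(loc["notum", notum_cols]), 0.7)
  expect_gte(sum(loc["notum", pos$domain == "notum"]),
             2 * sum(loc["notum", pos$domain == "pouch"]))
  # single-cell cluster returns its own weight row
  one <- cluster_localization(res, c("z", rep("rest", sum(epi) - 1)))
  expect_equal(unname(one["z", ]), unname(res$weights[1, ]))
})
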