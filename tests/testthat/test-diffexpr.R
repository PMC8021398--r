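nm_two_groups <- function(a_vals, b_vals, gene = "g1") {
  toy_norm(matrix(c(a_vals, b_vals), nrow = 1),
           genes = gene,
           cells = c(sprintf("a%d", seq_along(a_vals)),
                     sprintf("b%d", seq_along(b_vals))))
}

test_that("small-sample p-values match exhaustive enumeration", {
  nm <- nm_two_groups(c(1, 2, 3), c(4, 5, 6))
  tab <- wilcoxon_de(nm, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(tab$p, 0.1, tolerance = 1e-12)
  expect_equal(tab$p, wilcox_p_enum(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  # random untied draws: exact path equals the enumeration oracle
  set.seed(31)
  for (i in 1:10) {
    v <- sample(1000, 9)                      # distinct values, no ties
    a <- v[1:4]; b <- v[5:9]
    nm_i <- nm_two_groups(a, b)
    got <- wilcoxon_de(nm_i, sprintf("a%d", 1:4), sprintf("b%d", 1:5))$p
    expect_equal(got, wilcox_p_enum(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum agrees with stats::wilcox.test on larger tied data", {
  set.seed(17)
  a <- rpois(40, 2); b <- rpois(60, 3)
  nm <- nm_two_groups(a, b)
  got <- wilcoxon_de(nm, sprintf("a%d", 1:40), sprintf("b%d", 1:60))
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$stat, unname(ref$statistic))
})

test_that("identical groups give p = 1 and lnFC 0; fold-change closed form", {
  nm <- nm_two_groups(c(1, 2, 3), c(1, 2, 3))
  tab <- wilcoxon_de(nm, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(tab$lnfc, 0)
  expect_equal(tab$p, 1)
  # expm1-mean 2 in A vs all-zero B -> ln(3/1)
  a <- log1p(c(1, 2, 3))                        # expm1 mean = 2
  nm2 <- nm_two_groups(a, c(0, 0, 0))
  tab2 <- wilcoxon_de(nm2, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(tab2$lnfc, log(3), tolerance = 1e-12)
  expect_equal(tab2$pct_a, 1)
  expect_equal(tab2$pct_b, 0)
})

test_that("test and fold-change are antisymmetric in the group order", {
  set.seed(23)
  m <- matrix(rpois(50 * 30, 2), 50, 30)
  nm <- toy_norm(log1p(m))
  a <- nm$cell_ids[1:12]; b <- nm$cell_ids[13:30]
  t_ab <- wilcoxon_de(nm, a, b)
  t_ba <- wilcoxon_de(nm, b, a)
  expect_equal(t_ab$p, t_ba$p, tolerance = 1e-12)
  expect_equal(t_ab$lnfc, -t_ba$lnfc, tolerance = 1e-12)
  expect_error(wilcoxon_de(nm, a, c(b, a[1])), "overlap")
  expect_error(wilcoxon_de(nm, a[1:2], b), "at least 3")
})

test_that("exact and approximate paths agree for n=5 vs 5", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    nm <- nm_two_groups(a, b)
    p_exact <- wilcoxon_de(nm, sprintf("a%d", 1:5), sprintf("b%d", 1:5))$p
    # approximate path forced via a duplicated dummy gene with ties
    r <- rank(c(a, b))
    u <- sum(r[1:5]) - 15
    z <- (u - 12.5 - sign(u - 12.5) * 0.5) / sqrt(5 * 5 * 11 / 12)
    p_norm <- min(1, 2 * pnorm(-abs(z)))
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("BH adjustment reproduces the step-up worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the three-part criterion applies its boundary semantics", {
  tab <- data.frame(gene = c("in", "out_fdr", "out_small"),
                    stat = 0, p = 0,
                    fdr = c(0.04, 0.05, 0.01),
                    lnfc = c(0.15, 1.0, 0.10),
                    pct_a = c(0.15, 0.9, 0.9), pct_b = c(0.01, 0.9, 0.9))
  kept <- call_significant(tab, de_thresholds())
  expect_identical(kept$gene, "in")            # inclusive lnFC/pct bounds
  expect_false("out_fdr" %in% kept$gene)       # strict FDR < 0.05
  expect_equal(nrow(call_significant(tab[0, ], de_thresholds())), 0L)
})

test_that("one-vs-all marker tables mirror fold-change signs", {
  set.seed(19)
  m <- matrix(rpois(40 * 30, 2), 40, 30)
  m[1:5, 1:15] <- m[1:5, 1:15] + 5
  nm <- toy_norm(log1p(m))
  res <- one_vs_all_markers(nm, rep(c("x", "y"), each = 15))
  expect_equal(res$x$table$lnfc, -res$y$table$lnfc, tolerance = 1e-12)
  expect_true(all(sprintf("g%02d", 1:5) %in% res$x$significant$gene))
  expect_warning(
    one_vs_all_markers(nm, c("solo", rep(c("x", "y"), c(14, 15)))),
    "fewer than 3")
})

test_that("planted markers are recovered with few false positives", {
  set.seed(29)
  g <- 800; n <- 300
  m <- matrix(rnbinom(g * n, mu = 2, size = 2), g, n)
  planted <- seq_len(50)
  m[planted, 1:100] <- rnbinom(50 * 100, mu = 4, size = 2)
  nm <- toy_norm(log1p(m))
  res <- one_vs_all_markers(nm, rep(c("a", "b"), c(100, 200)))
  hits <- res$a$significant$gene[res$a$significant$lnfc > 0]
  expect_gte(length(intersect(sprintf("g%02d", planted), hits)) / 50, 0.9)
  fp <- setdiff(res$a$significant$gene, sprintf("g%02d", planted))
  expect_lte(length(fp) / (g - 50), 0.01)
})

test_that("temporal consistency keeps all-batch shifts, drops artifacts", {
  cfg <- disc_sim_config(n_cells_per_batch = 1250, doublet_rate = 0,
                         amp_fraction = 1, seed = 33)
  b <- simulate_disc(cfg)
  nm <- normalize_total_log(b$counts)
  res <- temporal_consistent_de(nm, b$counts$cell_ids)
  up <- sprintf("tmp_up_%02d", 1:10)
  dn <- sprintf("tmp_dn_%02d", 1:10)
  art <- sprintf("art_%02d", 1:5)
  expect_true(all(c(up, dn) %in% res$table$gene))
  expect_false(any(art %in% res$table$gene))
  # planted late-up genes: early-vs-late lnFC negative in every pair
  expect_true(all(res$table$ln_avg_fc[res$table$gene %in% up] < 0))
  expect_true(all(res$table$ln_avg_fc[res$table$gene %in% dn] > 0))
  expect_equal(unique(res$table$n_pairs), 4L)
})

test_that("the linear-average fold change reduces to the common lnFC", {
  # identical per-pair ratios e^0.5 -> ln of their mean is 0.5
  lnfc <- rep(0.5, 4)
  expect_equal(log(mean(exp(lnfc))), 0.5)
  # and the implementation reports it that way on real tables
  cfg <- disc_sim_config(n_cells_per_batch = 150, doublet_rate = 0,
                         amp_fraction = 1, batch_scale = 0, seed = 35)
  b <- simulate_disc(cfg)
  nm <- normalize_total_log(b$counts)
  res_lin <- temporal_consistent_de(nm, b$counts$cell_ids)
  res_log <- temporal_consistent_de(nm, b$counts$cell_ids, average = "log")
  shared <- intersect(res_lin$table$gene, res_log$table$gene)
  i <- match(shared, res_lin$table$gene); j <- match(shared, res_log$table$gene)
  # ln(mean ratio) >= mean(lnFC) by Jensen, equal when pairs agree
  expect_true(all(res_lin$table$ln_avg_fc[i] >=
                    res_log$table$ln_avg_fc[j] - 1e-12))
})

test_that("under the global null the rank-sum test is calibrated", {
  set.seed(37)
  g <- 2000; n <- 100
  m <- matrix(rnbinom(g * 2 * n, mu = 5, size = 5), g, 2 * n)
  nm <- toy_norm(log1p(m))
  tab <- wilcoxon_de(nm, nm$cell_ids[1:n], nm$cell_ids[n + 1:n])
  expect_lt(abs(mean(tab$p < 0.05) - 0.05), 0.01)
})
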