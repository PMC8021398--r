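test_that("variable-gene ranking is monotone in variance and skips constants", {
  set.seed(2)
  n <- 60
  base <- matrix(rpois(50 * n, 5), 50, n)
  base[1, ] <- 5                                # constant gene
  base[2, ] <- rpois(n, 5)                      # same mean, poisson var
  base[3, ] <- 5 + (rbinom(n, 1, 0.5) * 2 - 1) * 4  # same mean, higher var
  cm <- toy_counts(base)
  sel <- select_variable_genes(cm, 10)
  expect_false("g01" %in% sel)
  expect_true("g03" %in% sel)
})

test_that("planted high-variance genes are recovered per batch", {
  set.seed(8)
  n <- 400; g <- 500
  m <- matrix(rpois(g * n, 2), g, n)
  hot <- seq_len(50)
  # overdispersed planted genes: same scale, far larger variance
  m[hot, ] <- matrix(rnbinom(50 * n, mu = 2, size = 0.1), 50, n)
  cm <- toy_counts(m, batch = rep(c("b1", "b2"), each = n / 2))
  sel <- select_variable_genes(cm, 100)
  expect_gte(length(intersect(sprintf("g%02d", hot), sel)), 45)
})

test_that("the built-in embedding is shaped, deterministic, and batch-robust", {
  set.seed(5)
  g <- 80; n <- 300
  m <- matrix(rpois(g * n, 4), g, n)
  batch <- rep(c("b1", "b2"), each = n / 2)
  # batch 2: global per-gene multiplicative shift
  m[, batch == "b2"] <- m[, batch == "b2"] + rep(rpois(g, 3), n / 2)
  cm <- toy_counts(m, batch = batch)
  genes <- cm$gene_ids
  lat1 <- embed_cells(cm, genes, embed_params(20, seed = 3))
  lat2 <- embed_cells(cm, genes, embed_params(20, seed = 3))
  expect_equal(dim(lat1$coordinates), c(n, 20L))
  expect_identical(lat1$coordinates, lat2$coordinates)
  # after within-batch standardization no single dim separates the batches
  auc <- apply(lat1$coordinates, 2, function(d) {
    r <- rank(d)
    n1 <- sum(batch == "b1")
    u <- sum(r[batch == "b1"]) - n1 * (n1 + 1) / 2
    u / (n1 * (n - n1))
  })
  expect_lt(max(abs(auc - 0.5)) + 0.5, 0.6)
  expect_error(embed_cells(cm, genes, embed_params(20, provider = "nope")),
               "unknown embedding provider")
})

test_that("SNN clustering recovers well-separated blobs exactly", {
  set.seed(7)
  x <- rbind(matrix(rnorm(500 * 5), ncol = 5),
             matrix(rnorm(500 * 5, mean = 10), ncol = 5))
  lat <- latent_space(x)
  cl <- snn_cluster(lat, resolution = 0.5, k = 20, seed = 1)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(ari(cl, rep(1:2, each = 500)), 1.0)
  # resolution monotonicity and determinism
  n_hi <- length(unique(snn_cluster(lat, resolution = 4, seed = 1)))
  n_lo <- length(unique(snn_cluster(lat, resolution = 0.5, seed = 1)))
  expect_gte(n_hi, n_lo)
  expect_identical(snn_cluster(lat, resolution = 2, seed = 9),
                   snn_cluster(lat, resolution = 2, seed = 9))
  expect_error(snn_cluster(latent_space(x[1:10, ]), k = 20), "more cells")
})

test_that("sex classification thresholds a bimodal gene and defaults female", {
  nm <- toy_norm(rbind(c(0, 0, 0, 3, 3), rep(0, 5)),
                 genes = c("roX1", "roX2"))
  res <- classify_sex(nm)
  expect_gt(res$thresholds["roX1"], 0)
  expect_lt(res$thresholds["roX1"], 3)
  expect_equal(unname(res$sex), c(rep("female", 3), rep("male", 2)))
  expect_true(is.na(res$thresholds["roX2"]))   # flat gene: no minimum

  nm0 <- toy_norm(matrix(0, 2, 4), genes = c("roX1", "roX2"))
  expect_true(all(classify_sex(nm0)$sex == "female"))
  expect_error(classify_sex(toy_norm(matrix(1, 2, 4))), "no sex gene")
})

test_that("sex classification is invariant to cell order and extra genes", {
  set.seed(12)
  n <- 500
  male <- rbinom(n, 1, 0.4) == 1
  v1 <- ifelse(male, rnorm(n, 2.5, 0.5), 0)
  m <- rbind(v1, 0, matrix(rexp(3 * n), 3))
  nm <- toy_norm(m, genes = c("roX1", "roX2", "x1", "x2", "x3"))
  r1 <- classify_sex(nm)
  perm <- sample(n)
  nm_p <- toy_norm(m[, perm],
                   genes = c("roX1", "roX2", "x1", "x2", "x3"),
                   cells = nm$cell_ids[perm])
  r2 <- classify_sex(nm_p)
  expect_equal(r1$sex[nm$cell_ids], r2$sex[nm$cell_ids])
})

test_that("cell-cycle masking removes the one correlated dimension", {
  set.seed(6)
  n <- 400
  phase <- rbinom(n, 1, 0.5)
  cc_expr <- matrix(rep(phase * 2, 5), 5, n, byrow = TRUE) +
    matrix(rnorm(5 * n, sd = 0.3), 5, n)
  nm <- toy_norm(pmax(cc_expr, 0), genes = sprintf("cc%d", 1:5))
  lat <- latent_space(cbind(matrix(rnorm(n * 2), n, 2),
                            scale(colMeans(cc_expr))[, 1] * 3 + rnorm(n, sd = 0.1),
                            matrix(rnorm(n * 2), n, 2)))
  out <- mask_cell_cycle_dimension(lat, nm, sprintf("cc%d", 1:5))
  expect_identical(out$masked_dims, 3L)
  expect_lte(length(out$masked_dims), 1)
  # independent dims: nothing masked
  lat2 <- latent_space(matrix(rnorm(n * 5), n, 5))
  out2 <- mask_cell_cycle_dimension(lat2, nm, sprintf("cc%d", 1:5))
  expect_identical(out2$masked_dims, integer(0))
  expect_error(mask_cell_cycle_dimension(lat, toy_norm(matrix(1, 5, n),
                                                       genes = sprintf("cc%d", 1:5)),
                                         sprintf("cc%d", 1:5)),
               "constant")
})

test_that("cluster annotation scores marker sets and breaks ties in order", {
  sc <- rbind(SPARC = c(2, 2, -1, -1), twi = c(2, 2, -1, -1),
              Fas3 = c(-1, -1, 2, 2))
  colnames(sc) <- sprintf("c%d", 1:4)
  ann <- annotate_clusters(sc, c(1, 1, 2, 2),
                           list(AMP = c("SPARC", "twi"), epithelium = "Fas3"))
  expect_equal(ann$label[ann$cluster == "1"], "AMP")
  expect_equal(ann$label[ann$cluster == "2"], "epithelium")
  # exact tie -> first type in table order, flagged
  sc_tie <- rbind(a = c(1, 1), b = c(1, 1))
  ann2 <- annotate_clusters(sc_tie, c(1, 1), list(t1 = "a", t2 = "b"))
  expect_equal(ann2$label, "t1")
  expect_true(ann2$tie)
})

test_that("compartment calls follow marker means with anterior ties", {
  nm <- toy_norm(rbind(c(2, 0), c(1, 0), c(0, 0)),
                 genes = c("hh", "en", "ci"))
  cp <- classify_compartment(nm)
  expect_equal(unname(cp), c("posterior", "anterior"))
})

test_that("AMP subtype calls compare ct and vg with strict inequality", {
  sc <- rbind(ct = c(1.2, 1.2, 0, 0), vg = c(-0.8, -0.8, 0, 0))
  colnames(sc) <- sprintf("c%d", 1:4)
  res <- classify_amp_type(sc, c("a", "a", "b", "b"))
  expect_equal(res$amp_type[res$cluster == "a"], "direct")
  expect_equal(res$amp_type[res$cluster == "b"], "indirect")  # tie rule
})

test_that("sex-stratified batches remove sex separability in latent space", {
  cfg <- disc_sim_config(n_cells_per_batch = 600, doublet_rate = 0, seed = 14)
  b <- simulate_disc(cfg)
  amp_ids <- b$truth$cell_id[b$truth$layer == "AMP"]
  cm <- subset_cells(b$counts, amp_ids)
  sex <- b$truth[amp_ids, "sex"]
  cm$cell_meta$batch <- paste(cm$cell_meta$batch, sex, sep = "_")
  vg <- select_variable_genes(cm, 2000)
  lat <- embed_cells(cm, vg, embed_params(20, seed = 1))
  auc <- apply(lat$coordinates, 2, function(d) {
    r <- rank(d); n1 <- sum(sex == "male")
    u <- sum(r[sex == "male"]) - n1 * (n1 + 1) / 2
    u / (n1 * (length(sex) - n1))
  })
  expect_lt(max(abs(auc - 0.5)) + 0.5, 0.65)
})
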