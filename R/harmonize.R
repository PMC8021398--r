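#' Embedding parameters
#'
#' @param n_latent number of latent dimensions (default 20).
#' @param variable_genes_per_batch variable genes selected within each batch
#'   before taking the union (1000 for epithelial subsets, 2000 for AMP
#'   subsets in the reference analysis).
#' @param provider embedding provider id (see [register_embedding_provider()]);
#'   default `"svd"`, the built-in deterministic provider.
#' @param seed integer seed forwarded to the provider.
#' @return an `EmbedParams` list.
#' @export
embed_params <- function(n_latent = 20, variable_genes_per_batch = 2000,
                         provider = "svd", seed = 1L) {
  if (n_latent < 2) stop("n_latent must be at least 2")
  structure(list(n_latent = n_latent,
                 variable_genes_per_batch = variable_genes_per_batch,
                 provider = provider, seed = as.integer(seed)),
            class = "EmbedParams")
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection: within each batch, a loess fit of
#' log10(variance) on log10(mean) over raw counts gives each gene an
#' expected standard deviation; counts are standardized against it, clipped
#' at sqrt(n_cells), and genes are ranked by the variance of the clipped
#' standardized values.  The per-batch top `n_per_batch` sets are unioned.
#'
#' @param cm a `CountMatrix`.
#' @param n_per_batch genes retained per batch before the union.
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return character vector: the union of per-batch variable gene ids.
#' @export
select_variable_genes <- function(cm, n_per_batch = 2000, loess_span = 0.3) {
  batches <- split_in_order(seq_along(cm$cell_ids), cm$cell_meta$batch)
  sel <- lapply(batches, function(idx) {
    if (length(idx) < 2) stop("batch with fewer than 2 cells")
    x <- cm$counts[, idx, drop = FALSE]
    n <- length(idx)
    mu <- Matrix::rowSums(x) / n
    ex2 <- Matrix::rowSums(x^2) / n
    v <- (ex2 - mu^2) * n / (n - 1)
    use <- mu > 0 & v > 0
    fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = loess_span,
                        degree = 2)
    sd_exp <- rep(NA_real_, length(mu))
    sd_exp[use] <- sqrt(10^stats::predict(fit))
    clip <- sqrt(n)
    std_var <- rep(0, length(mu))
    xs <- Matrix::t(methods::as(x, "CsparseMatrix"))  # cells x genes
    for (g in which(use)) {
      vals <- xs[, g]
      z <- pmin((vals - mu[g]) / sd_exp[g], clip)
      z <- pmax(z, -clip)
      std_var[g] <- sum((z - mean(z))^2) / (n - 1)
    }
    cm$gene_ids[order(std_var, decreasing = TRUE)[seq_len(min(n_per_batch,
                                                              sum(use)))]]
  })
  Reduce(union, sel)
}

# provider registry --------------------------------------------------------
.providers <- new.env(parent = emptyenv())

#' Register an embedding provider
#'
#' Providers turn a `CountMatrix` plus a gene set into an `n_latent`-d
#' latent space.  The built-in `"svd"` provider natural-log normalizes,
#' standardizes each gene within each batch (removing additive per-batch
#' shifts) and takes a truncated SVD.  External models (e.g., a variational
#' autoencoder) can be plugged in behind the same contract.
#'
#' @param id provider id.
#' @param fn function `(cm, gene_set, params)` returning a cells x n_latent
#'   numeric matrix.
#' @export
register_embedding_provider <- function(id, fn) {
  stopifnot(is.character(id), is.function(fn))
  assign(id, fn, envir = .providers)
  invisible(id)
}

.svd_provider <- function(cm, gene_set, params) {
  nm <- normalize_total_log(cm)
  gi <- match(gene_set, nm$gene_ids)
  v <- as.matrix(nm$values[gi, , drop = FALSE])
  for (idx in split_in_order(seq_along(cm$cell_ids), cm$cell_meta$batch)) {
    b <- v[, idx, drop = FALSE]
    mu <- rowMeans(b)
    sdv <- apply(b, 1, stats::sd)
    sdv[sdv == 0] <- 1
    v[, idx] <- (b - mu) / sdv
  }
  x <- t(v)                               # cells x genes
  k <- params$n_latent
  cp <- crossprod(x)                      # genes x genes
  ev <- eigen(cp, symmetric = TRUE)
  if (ev$values[k] <= max(ev$values) * 1e-12)
    stop("n_latent exceeds the rank of the data")
  load <- ev$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive, for determinism
  for (j in seq_len(k)) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) load[, j] <- -load[, j]
  }
  coords <- x %*% load
  rownames(coords) <- cm$cell_ids
  coords
}

#' Embed cells into a latent space
#'
#' @param cm a `CountMatrix`.
#' @param gene_set non-empty character vector of genes the embedding uses
#'   (typically from [select_variable_genes()]).
#' @param params an [embed_params()] object.
#' @return a `LatentSpace`: list with `coordinates` (cells x n_latent),
#'   `masked_dims` (initially empty integer vector), `provider`.
#' @export
embed_cells <- function(cm, gene_set, params = embed_params()) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  miss <- setdiff(gene_set, cm$gene_ids)
  if (length(miss)) stop("gene_set genes absent: ",
                         paste(head(miss, 5), collapse = ", "))
  if (!exists(params$provider, envir = .providers))
    stop("unknown embedding provider: ", params$provider)
  fn <- get(params$provider, envir = .providers)
  set.seed(params$seed)
  coords <- fn(cm, gene_set, params)
  stopifnot(nrow(coords) == length(cm$cell_ids),
            ncol(coords) == params$n_latent)
  latent_space(coords)
}

#' Construct a LatentSpace
#' @param coordinates cells x d matrix.
#' @param masked_dims integer indices of dimensions excluded downstream.
#' @return a `LatentSpace` list.
#' @export
latent_space <- function(coordinates, masked_dims = integer(0)) {
  stopifnot(is.matrix(coordinates),
            all(masked_dims >= 1), all(masked_dims <= ncol(coordinates)))
  structure(list(coordinates = coordinates,
                 masked_dims = as.integer(masked_dims)),
            class = "LatentSpace")
}

#' Active (unmasked) coordinates of a latent space
#' @param latent a `LatentSpace`.
#' @return the coordinate matrix with masked dimensions dropped.
#' @export
active_coords <- function(latent) {
  d <- ncol(latent$coordinates)
  keep <- setdiff(seq_len(d), latent$masked_dims)
  latent$coordinates[, keep, drop = FALSE]
}

# blocked exact kNN in low-dimensional space
.knn_indices <- function(x, k, block = 1000L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf    # exclude self
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on the active latent dimensions
#' (Euclidean), weights cell pairs by the Jaccard overlap of their
#' neighborhoods (pruned below `prune`), and partitions the graph by
#' modularity-based Louvain community detection at the given resolution.
#'
#' @param latent a `LatentSpace`; masked dimensions are excluded.
#' @param resolution modularity resolution (default 2.0).
#' @param k neighbors per cell (default 20).
#' @param prune SNN weights below this Jaccard value are dropped
#'   (default 1/15).
#' @param seed RNG seed for the community search.
#' @return integer-coded factor of cluster labels, one per cell.
#' @export
snn_cluster <- function(latent, resolution = 2.0, k = 20, prune = 1 / 15,
                        seed = 1L) {
  x <- active_coords(latent)
  n <- nrow(x)
  if (n <= k) stop("need more cells than neighbors (k)")
  nn <- .knn_indices(x, k)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  counts <- Matrix::tcrossprod(adj)          # shared neighbors
  counts <- methods::as(counts, "CsparseMatrix")
  jac <- counts
  jac@x <- jac@x / (2 * k - jac@x)           # |A n B| / |A u B|
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(cl)
  factor(as.integer(labels))
}
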