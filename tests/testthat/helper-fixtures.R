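# shared builders for small in-code fixtures

# CountMatrix from a dense matrix, auto ids
toy_counts <- function(m, genes = NULL, cells = NULL, batch = "b1",
                       time = NA_character_) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  count_matrix(m, genes, cells,
               data.frame(batch = rep(batch, length.out = ncol(m)),
                          time = rep(time, length.out = ncol(m)),
                          stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NormMatrix directly from a dense value matrix (values already log-normalized)
toy_norm <- function(m, genes = NULL, cells = NULL, batch = "b1",
                     time = NA_character_) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  v <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(v) <- list(genes, cells)
  structure(list(values = v, gene_ids = genes, cell_ids = cells,
                 cell_meta = data.frame(
                   batch = rep(batch, length.out = length(cells)),
                   time = rep(time, length.out = length(cells)),
                   row.names = cells, stringsAsFactors = FALSE),
                 scale_factor = 10000),
            class = "NormMatrix")
}

# CellStats from raw vectors
toy_stats <- function(n_gene, pct_mito = 0, cells = NULL) {
  cells <- cells %||% sprintf("c%02d", seq_along(n_gene))
  out <- data.frame(cell_id = cells, n_gene = n_gene,
                    total_umi = pmax(n_gene, 1L),
                    pct_mito = rep(pct_mito, length.out = length(n_gene)),
                    stringsAsFactors = FALSE)
  class(out) <- c("CellStats", "data.frame")
  out
}

# brute-force MCC via explicit 2x2 contingency (independent oracle)
mcc_brute <- function(a, b) {
  tp <- sum(a == 1 & b == 1); tn <- sum(a == 0 & b == 0)
  fp <- sum(a == 1 & b == 0); fn <- sum(a == 0 & b == 1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# exact two-sided rank-sum p by enumeration of all group assignments
wilcox_p_enum <- function(a, b) {
  vals <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(vals), na)
  obs <- sum(rank(vals)[seq_len(na)])
  perms <- apply(idx, 2, function(i) sum(rank(vals)[i]))
  mu <- mean(perms)
  mean(abs(perms - mu) >= abs(obs - mu) - 1e-9)
}

# a small single-layer reference with given binary patterns
flat_reference <- function(patterns) {
  p <- ncol(patterns)
  layered_reference(
    data.frame(id = sprintf("p%03d", seq_len(p)), layer = "DP",
               x = seq_len(p), y = 0, stringsAsFactors = FALSE),
    `colnames<-`(patterns, sprintf("p%03d", seq_len(p))))
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
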