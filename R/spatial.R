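#' Construct and validate a layered spatial reference
#'
#' @param positions data.frame with columns `id`, `layer` (one of
#'   `"AMP"`, `"DP"`, `"PE"`), `x`, `y`; extra annotation columns are kept.
#' @param patterns binary landmark-gene x position matrix; column names
#'   must equal the position ids.
#' @return a `LayeredReference` list.
#' @export
layered_reference <- function(positions, patterns) {
  need <- c("id", "layer", "x", "y")
  if (!all(need %in% names(positions)))
    stop("positions needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(positions$id)) stop("duplicate position ids")
  if (!all(positions$layer %in% c("AMP", "DP", "PE")))
    stop("layer must be one of AMP, DP, PE")
  patterns <- as.matrix(patterns)
  if (!identical(colnames(patterns), positions$id)) {
    if (is.null(colnames(patterns)) ||
        !setequal(colnames(patterns), positions$id)) {
      miss <- setdiff(positions$id, colnames(patterns))
      stop("pattern columns do not match position ids",
           if (length(miss)) paste0("; missing: ",
                                    paste(head(miss, 5), collapse = ", ")))
    }
    patterns <- patterns[, positions$id, drop = FALSE]
  }
  if (!all(patterns %in% c(0, 1))) stop("patterns must be binary (0/1)")
  if (is.null(rownames(patterns))) stop("patterns need landmark gene names")
  structure(list(positions = positions, patterns = patterns),
            class = "LayeredReference")
}

#' @export
print.LayeredReference <- function(x, ...) {
  cat(sprintf("LayeredReference: %d positions (%s), %d landmark genes\n",
              nrow(x$positions),
              paste(sprintf("%s=%d", names(table(x$positions$layer)),
                            table(x$positions$layer)), collapse = ", "),
              nrow(x$patterns)))
  invisible(x)
}

#' Read a layered reference from positions and patterns TSVs
#'
#' @param positions_tsv TSV with header `id, layer, x, y` (extra columns
#'   allowed).
#' @param patterns_tsv TSV: first column `gene`, remaining columns one per
#'   position id, entries 0/1.
#' @return a `LayeredReference`.
#' @export
load_reference <- function(positions_tsv, patterns_tsv) {
  pos <- read.delim(positions_tsv, stringsAsFactors = FALSE,
                    check.names = FALSE)
  pat <- read.delim(patterns_tsv, stringsAsFactors = FALSE,
                    check.names = FALSE)
  genes <- pat[[1]]
  m <- as.matrix(pat[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric pattern entries")
  rownames(m) <- genes
  layered_reference(pos, m)
}

#' Write a layered reference as TSV files
#' @param ref a `LayeredReference`.
#' @param positions_tsv,patterns_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, positions_tsv, patterns_tsv) {
  write.table(ref$positions, positions_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pat <- data.frame(gene = rownames(ref$patterns), ref$patterns,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(pat, patterns_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(positions_tsv, patterns_tsv))
}

# nearest-rank ("higher") empirical quantile
.quantile_higher <- function(values, q) {
  n <- length(values)
  k <- ceiling(q * n)
  if (k <= 0) return(min(values))
  sort(values)[k]
}

#' Binarize cells against the reference's positive fractions
#'
#' For each landmark gene, the fraction `f` of the layer's positions whose
#' pattern is 1 determines a threshold: the `(1 - f)` empirical quantile
#' (nearest-rank, "higher" convention) of the gene's values over the cells
#' being mapped.  A cell is positive when its value strictly exceeds the
#' threshold, so the positive fraction of cells approximately matches the
#' positive fraction of reference positions.
#'
#' @param nm a `NormMatrix` restricted to the cells being mapped.
#' @param ref a `LayeredReference`.
#' @param layer layer (or layers, e.g. `c("DP", "PE")`) whose positions
#'   define the positive fractions.
#' @return binary cells x landmark-genes matrix.
#' @export
binarize_cells <- function(nm, ref, layer) {
  genes <- rownames(ref$patterns)
  miss <- setdiff(genes, nm$gene_ids)
  if (length(miss)) stop("landmark genes missing from matrix: ",
                         paste(miss, collapse = ", "))
  cols <- ref$positions$layer %in% layer
  if (!any(cols)) stop("no positions in layer ", paste(layer, collapse = "/"))
  f <- rowMeans(ref$patterns[, cols, drop = FALSE])
  x <- as.matrix(nm$values[genes, , drop = FALSE])
  out <- matrix(0L, ncol(x), length(genes),
                dimnames = list(nm$cell_ids, genes))
  for (i in seq_along(genes)) {
    t_g <- .quantile_higher(x[i, ], 1 - f[i])
    out[, i] <- as.integer(x[i, ] > t_g)
  }
  out
}

#' Matthews correlation scores between cells and reference positions
#'
#' For every (cell, position) pair, the MCC of the 2x2 contingency table
#' comparing the cell's binary landmark vector with the position's pattern:
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  Any zero factor
#' in the denominator yields a score of 0 (uninformative).
#'
#' @param cell_binary binary cells x landmark-genes matrix
#'   (see [binarize_cells()]); columns must match the reference's landmark
#'   gene order.
#' @param ref a `LayeredReference`.
#' @param layer layer(s) to score against.
#' @return cells x positions score matrix with values in `[-1, 1]`.
#' @export
mcc_scores <- function(cell_binary, ref, layer) {
  cols <- ref$positions$layer %in% layer
  pat <- ref$patterns[, cols, drop = FALSE]
  if (!identical(colnames(cell_binary), rownames(pat)))
    stop("landmark gene order differs between cells and reference")
  b <- cell_binary
  tp <- b %*% pat
  fp <- (1 - b) %*% pat        # position 1, cell 0 -> miss for the cell
  fn <- b %*% (1 - pat)
  tn <- (1 - b) %*% (1 - pat)
  num <- tp * tn - fn * fp
  den2 <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  s <- matrix(0, nrow(b), ncol(pat),
              dimnames = list(rownames(b), colnames(pat)))
  ok <- den2 > 0
  s[ok] <- num[ok] / sqrt(den2[ok])
  s
}

#' Convert scores to row-stochastic mapping weights
#'
#' Softmax per cell over its layer's positions:
#' `w(c, p) = exp(score(c, p) / tau)`, normalized to sum to 1 per cell.
#' Small `tau` concentrates mass on the best-scoring position; large `tau`
#' approaches uniform.
#'
#' @param scores cells x positions score matrix.
#' @param tau softmax temperature (default 0.1).
#' @return row-stochastic weight matrix of the same shape.
#' @export
mapping_weights <- function(scores, tau = 0.1) {
  stopifnot(tau > 0)
  if (any(!is.finite(scores))) stop("non-finite scores")
  e <- exp((scores - apply(scores, 1, max)) / tau)
  e / rowSums(e)
}

#' Virtual in situ: predicted spatial expression of a gene
#'
#' Distributes cells' expression over reference positions by the mapping
#' weights: `vish(p) = sum_c w(c,p) x(c) / sum_c w(c,p)`.  Positions with
#' zero total weight get `NA`.
#'
#' @param weights row-stochastic cells x positions matrix.
#' @param nm a `NormMatrix` covering the mapped cells (rows of `weights`).
#' @param gene gene id to predict.
#' @return named numeric vector over positions.
#' @export
virtual_insitu <- function(weights, nm, gene) {
  if (!gene %in% nm$gene_ids) stop("gene absent: ", gene)
  x <- as.numeric(nm$values[gene, rownames(weights)])
  tot <- colSums(weights)
  v <- as.numeric(crossprod(weights, x)) / tot
  v[tot == 0] <- NA_real_
  setNames(v, colnames(weights))
}

#' Map cells onto the layered reference
#'
#' AMP cells are scored against AMP-layer positions only; epithelial cells
#' against the disc proper plus peripodial positions (configurable).  The
#' two groups are binarized separately against their own layers' positive
#' fractions, scored by MCC and converted to softmax weights.  Weight mass
#' outside a cell's layer is exactly zero.
#'
#' @param nm a `NormMatrix` over the cells to map.
#' @param ref a `LayeredReference`.
#' @param cell_layer_labels per-cell labels, `"AMP"` or `"epithelium"`.
#' @param tau softmax temperature (default 0.1).
#' @param epithelium_layers reference layers epithelial cells map over
#'   (default `c("DP", "PE")`).
#' @return a `MappingResult`: `scores` and row-stochastic `weights`
#'   (cells x all positions; zero outside the cell's layer), `layer_used`
#'   per cell.
#' @export
map_layer <- function(nm, ref, cell_layer_labels, tau = 0.1,
                      epithelium_layers = c("DP", "PE")) {
  if (length(cell_layer_labels) != length(nm$cell_ids) ||
      anyNA(cell_layer_labels))
    stop("every cell needs a layer label (AMP or epithelium)")
  if (!all(cell_layer_labels %in% c("AMP", "epithelium")))
    stop("layer labels must be 'AMP' or 'epithelium'")
  n <- length(nm$cell_ids)
  p <- nrow(ref$positions)
  scores <- matrix(0, n, p, dimnames = list(nm$cell_ids, ref$positions$id))
  weights <- matrix(0, n, p, dimnames = dimnames(scores))
  groups <- list(AMP = "AMP", epithelium = epithelium_layers)
  for (grp in names(groups)) {
    cells <- which(cell_layer_labels == grp)
    if (length(cells) == 0) next
    sub <- subset_norm_cells(nm, cells)
    b <- binarize_cells(sub, ref, groups[[grp]])
    s <- mcc_scores(b, ref, groups[[grp]])
    w <- mapping_weights(s, tau)
    scores[cells, colnames(s)] <- s
    weights[cells, colnames(w)] <- w
  }
  structure(list(scores = scores, weights = weights,
                 layer_used = setNames(cell_layer_labels, nm$cell_ids)),
            class = "MappingResult")
}

# cell subset of a NormMatrix (internal)
subset_norm_cells <- function(nm, cells) {
  structure(list(values = nm$values[, cells, drop = FALSE],
                 gene_ids = nm$gene_ids,
                 cell_ids = nm$cell_ids[cells],
                 cell_meta = nm$cell_meta[cells, , drop = FALSE],
                 scale_factor = nm$scale_factor),
            class = "NormMatrix")
}

#' Per-cluster localization maps
#'
#' Averages the member cells' weight rows per cluster, giving a
#' per-position intensity that sums to 1 over positions.
#'
#' @param result a `MappingResult`.
#' @param clusters cluster label per mapped cell.
#' @return clusters x positions matrix of mean weights.
#' @export
cluster_localization <- function(result, clusters) {
  stopifnot(length(clusters) == nrow(result$weights))
  groups <- split_in_order(seq_along(clusters), clusters)
  out <- t(vapply(groups, function(idx)
    colMeans(result$weights[idx, , drop = FALSE]),
    numeric(ncol(result$weights))))
  colnames(out) <- colnames(result$weights)
  out
}
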