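#' Construct a CountMatrix
#'
#' The package's central container: a sparse genes x cells matrix of raw UMI
#' counts plus per-cell metadata.  Every downstream stage (QC, embedding,
#' differential expression, spatial mapping) consumes this object or a
#' normalized view of it.
#'
#' @param counts genes x cells matrix of non-negative integer counts (dense or
#'   any \pkg{Matrix} sparse class; stored as `dgCMatrix`).
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell barcodes (columns).
#' @param cell_meta data.frame of per-cell annotations, one row per cell.
#'   Must contain a `batch` column; a `time` column and annotation slots
#'   (`layer`, `sex`, `cluster`, ...) may be added by pipeline stages.
#'
#' @return An object of class `CountMatrix` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, cell_meta) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids))
    stop("counts dimensions do not match gene/cell ids")
  if (any(counts@x < 0) || any(!is.finite(counts@x)))
    stop("counts must be finite and non-negative")
  if (any(counts@x != round(counts@x)))
    stop("counts must be integers")
  if (!is.data.frame(cell_meta) || nrow(cell_meta) != length(cell_ids))
    stop("cell_meta must be a data.frame with one row per cell")
  if (is.null(cell_meta$batch) || any(is.na(cell_meta$batch)))
    stop("every cell needs a batch label")
  dimnames(counts) <- list(gene_ids, cell_ids)
  rownames(cell_meta) <- cell_ids
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d batches\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cell_meta$batch))))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by cells (and optionally genes)
#'
#' @param cm a `CountMatrix`.
#' @param cells character cell ids or logical/integer index over cells.
#' @param genes optional gene ids or index over genes.
#' @return the subsetted `CountMatrix`.
#' @export
subset_cells <- function(cm, cells, genes = NULL) {
  if (is.character(cells)) cells <- match(cells, cm$cell_ids)
  if (is.logical(cells)) cells <- which(cells)
  if (anyNA(cells)) stop("unknown cell ids in subset")
  gi <- if (is.null(genes)) seq_along(cm$gene_ids) else {
    g <- if (is.character(genes)) match(genes, cm$gene_ids) else genes
    if (anyNA(g)) stop("unknown gene ids in subset")
    g
  }
  count_matrix(cm$counts[gi, cells, drop = FALSE],
               cm$gene_ids[gi], cm$cell_ids[cells],
               cm$cell_meta[cells, , drop = FALSE])
}

#' Combine CountMatrix objects over cells
#'
#' Genes must be identical across inputs (10x batches from one reference).
#' @param ... `CountMatrix` objects.
#' @return one combined `CountMatrix`.
#' @export
bind_cells <- function(...) {
  cms <- list(...)
  if (length(cms) == 1L && is.list(cms[[1]]) && !is(cms[[1]], "CountMatrix"))
    cms <- cms[[1]]
  genes <- cms[[1]]$gene_ids
  for (cm in cms) if (!identical(cm$gene_ids, genes))
    stop("gene ids differ between batches")
  meta_cols <- Reduce(union, lapply(cms, function(cm) names(cm$cell_meta)))
  metas <- lapply(cms, function(cm) {
    m <- cm$cell_meta
    for (col in setdiff(meta_cols, names(m))) m[[col]] <- NA
    m[, meta_cols, drop = FALSE]
  })
  count_matrix(do.call(cbind, lapply(cms, `[[`, "counts")), genes,
               unlist(lapply(cms, `[[`, "cell_ids"), use.names = FALSE),
               do.call(rbind, metas))
}

#' Read a 10x-style Matrix Market count triplet
#'
#' Reads `matrix.mtx` (coordinate format, genes as rows), a features TSV
#' (gene ids in the first column) and a barcodes TSV, and stamps a batch
#' label on every cell.
#'
#' @param matrix_path path to the Matrix Market file.
#' @param features_path path to the features TSV (one gene per line).
#' @param barcodes_path path to the barcodes TSV (one barcode per line).
#' @param batch_label batch label applied to all cells.
#' @param time_label optional time-point label applied to all cells.
#' @return a `CountMatrix`.
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path,
                            batch_label, time_label = NA_character_) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  feats <- read.delim(features_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  bcs <- read.delim(barcodes_path, header = FALSE,
                    stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feats))
    stop(sprintf("dimension mismatch: %s has %d rows but %s lists %d features",
                 matrix_path, nrow(m), features_path, length(feats)))
  if (ncol(m) != length(bcs))
    stop(sprintf("dimension mismatch: %s has %d columns but %s lists %d barcodes",
                 matrix_path, ncol(m), barcodes_path, length(bcs)))
  if (anyDuplicated(feats))
    stop("duplicate gene id in ", features_path)
  xs <- if (is(m, "sparseMatrix")) methods::as(m, "CsparseMatrix")@x else as.numeric(m)
  if (any(xs != round(xs)))
    stop("non-integer entries in ", matrix_path)
  count_matrix(m, feats, bcs,
               data.frame(batch = rep(batch_label, length(bcs)),
                          time = rep(time_label, length(bcs)),
                          stringsAsFactors = FALSE))
}

#' Write a CountMatrix as a Matrix Market triplet
#'
#' Inverse of [read_counts_mtx()]; follows the 10x layout (features as rows).
#'
#' @param cm a `CountMatrix`.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix for the three files.
#' @return invisibly, the three paths written.
#' @export
write_counts_mtx <- function(cm, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "features.tsv",
                                           "barcodes.tsv")))
  m <- cm$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, paths[1])
  writeLines(cm$gene_ids, paths[2])
  writeLines(cm$cell_ids, paths[3])
  invisible(paths)
}

#' Total-count normalization on the natural-log scale
#'
#' Each cell's counts are divided by its total UMIs, multiplied by
#' `scale_factor` (default 10,000), and transformed as `log1p`.  Cells with
#' zero total counts map to all-zero columns.
#'
#' @param cm a `CountMatrix`.
#' @param scale_factor positive scaling constant (default 10000).
#' @return a `NormMatrix`: list with sparse `values` (genes x cells),
#'   `gene_ids`, `cell_ids`, `cell_meta`, `scale_factor`.
#' @export
normalize_total_log <- function(cm, scale_factor = 10000) {
  stopifnot(scale_factor > 0)
  totals <- Matrix::colSums(cm$counts)
  inv <- ifelse(totals > 0, scale_factor / totals, 0)
  v <- cm$counts %*% Matrix::Diagonal(x = inv)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(cm$counts)
  structure(list(values = v, gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                 cell_meta = cm$cell_meta, scale_factor = scale_factor),
            class = "NormMatrix")
}

#' @export
print.NormMatrix <- function(x, ...) {
  cat(sprintf("NormMatrix: %d genes x %d cells (scale factor %g)\n",
              length(x$gene_ids), length(x$cell_ids), x$scale_factor))
  invisible(x)
}

#' Center and scale genes to unit variance
#'
#' Per gene, subtracts the mean across cells and divides by the sample
#' (n - 1) standard deviation, so each non-constant gene has mean 0 and SD 1.
#' Zero-variance genes map to all-zero rows.  Returns a dense matrix; an
#' optional symmetric clip is applied after scaling.
#'
#' @param nm a `NormMatrix` (or a plain genes x cells matrix).
#' @param clip optional positive number: scaled values are clamped to
#'   `[-clip, clip]`.  `NULL` (default) disables clipping.
#' @return dense genes x cells matrix of scaled values.
#' @export
scale_genes <- function(nm, clip = NULL) {
  v <- if (is(nm, "NormMatrix")) nm$values else nm
  if (ncol(v) < 2) stop("scaling needs at least 2 cells")
  x <- as.matrix(v)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  s <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  s[sdv == 0, ] <- 0
  if (!is.null(clip)) {
    stopifnot(clip > 0)
    s[s > clip] <- clip
    s[s < -clip] <- -clip
  }
  s
}

#' Per-cell QC statistics
#'
#' Computes the QC covariates the filtering stages use: the number of
#' detected genes (count > 0), the total UMI count, and the fraction of
#' counts coming from mitochondrial genes, identified by id prefix
#' (FlyBase convention `"mt:"`).
#'
#' @param cm a `CountMatrix`.
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return a `CellStats` data.frame with columns `cell_id`, `n_gene`,
#'   `total_umi`, `pct_mito` (fraction in `[0, 1]`).
#' @export
compute_cell_stats <- function(cm, mito_prefix = "mt:") {
  n_gene <- Matrix::colSums(cm$counts > 0)
  total <- Matrix::colSums(cm$counts)
  mito <- startsWith(cm$gene_ids, mito_prefix)
  mito_counts <- if (any(mito))
    Matrix::colSums(cm$counts[mito, , drop = FALSE]) else rep(0, ncol(cm$counts))
  out <- data.frame(cell_id = cm$cell_ids,
                    n_gene = as.integer(n_gene),
                    total_umi = as.integer(total),
                    pct_mito = ifelse(total > 0, mito_counts / total, 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("CellStats", "data.frame")
  out
}
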