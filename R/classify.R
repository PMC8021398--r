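#' Classify cells as male or female from dosage-compensation transcripts
#'
#' The roX noncoding RNAs are expressed almost exclusively in male cells, so
#' each sex gene's natural-log normalized expression is bimodal.  For each
#' gene a Gaussian kernel density (Silverman bandwidth, 512-point grid) is
#' estimated over all cells, and the leftmost strict interior local minimum
#' of the density is taken as that gene's threshold.  A cell is male iff its
#' value exceeds the threshold for *either* gene; a gene whose density has
#' no interior local minimum contributes no male calls.
#'
#' @param nm a `NormMatrix`.
#' @param sex_genes gene ids of the dosage-compensation transcripts
#'   (default `c("roX1", "roX2")`).
#' @return list with `sex` (named character vector, `"male"`/`"female"`)
#'   and `thresholds` (named numeric per gene; `NA` when the density is
#'   unimodal).
#' @export
classify_sex <- function(nm, sex_genes = c("roX1", "roX2")) {
  present <- intersect(sex_genes, nm$gene_ids)
  if (length(present) == 0)
    stop("no sex gene found among: ", paste(sex_genes, collapse = ", "))
  male <- rep(FALSE, length(nm$cell_ids))
  thresholds <- setNames(rep(NA_real_, length(present)), present)
  for (g in present) {
    vals <- as.numeric(nm$values[g, ])
    if (length(unique(vals)) < 2) next      # flat: no local minimum
    d <- stats::density(vals, bw = "nrd0", n = 512)
    y <- d$y
    interior <- which(y[2:511] < y[1:510] & y[2:511] < y[3:512]) + 1L
    if (length(interior) == 0) next
    thresholds[g] <- d$x[interior[1]]
    male <- male | (vals > thresholds[g])
  }
  list(sex = setNames(ifelse(male, "male", "female"), nm$cell_ids),
       thresholds = thresholds)
}

#' Per-cell summary score of a gene program
#'
#' Mean scaled (z-scored) expression of the gene set per cell; used for the
#' cell-cycle score.
#'
#' @param nm a `NormMatrix`.
#' @param gene_set gene ids (must be present).
#' @return numeric vector, one score per cell.
#' @export
program_score <- function(nm, gene_set) {
  miss <- setdiff(gene_set, nm$gene_ids)
  if (length(miss)) stop("genes absent: ", paste(miss, collapse = ", "))
  s <- scale_genes(subset_norm(nm, gene_set))
  colMeans(s)
}

#' Restrict a NormMatrix to a gene subset
#' @param nm a `NormMatrix`.
#' @param genes gene ids to keep (order preserved).
#' @return the restricted `NormMatrix`.
#' @export
subset_norm <- function(nm, genes) {
  gi <- match(genes, nm$gene_ids)
  structure(list(values = nm$values[gi, , drop = FALSE],
                 gene_ids = genes, cell_ids = nm$cell_ids,
                 cell_meta = nm$cell_meta, scale_factor = nm$scale_factor),
            class = "NormMatrix")
}

#' Mask the latent dimension tracking the cell cycle
#'
#' Computes a per-cell cell-cycle score (mean scaled expression of the
#' cell-cycle gene set), correlates every latent dimension with it, and
#' masks the single dimension with the largest |Pearson r| provided
#' |r| >= `r_threshold`; otherwise nothing is masked.  At most one
#' dimension is masked per call.
#'
#' @param latent a `LatentSpace`.
#' @param nm the matching `NormMatrix`.
#' @param cc_gene_set cell-cycle gene ids.
#' @param r_threshold minimum |r| for masking (default 0.5).
#' @return the `LatentSpace` with `masked_dims` updated, plus attribute
#'   `"cc_correlations"`: the per-dimension correlation table.
#' @export
mask_cell_cycle_dimension <- function(latent, nm, cc_gene_set,
                                      r_threshold = 0.5) {
  score <- program_score(nm, cc_gene_set)
  if (length(unique(score)) < 2)
    stop("cell-cycle score is constant; cannot correlate")
  r <- apply(latent$coordinates, 2, function(d) stats::cor(d, score))
  tab <- data.frame(dim = seq_along(r), r = r)
  best <- which.max(abs(r))
  masked <- if (abs(r[best]) >= r_threshold)
    union(latent$masked_dims, best) else latent$masked_dims
  out <- latent_space(latent$coordinates, masked)
  attr(out, "cc_correlations") <- tab
  out
}

#' Annotate clusters by marker-set scores
#'
#' Scores each cluster for each cell type as the mean scaled expression of
#' the type's marker set over the cluster's cells, and assigns the argmax.
#' Exact ties are broken by the declared order of `marker_table` and
#' flagged.
#'
#' @param scaled dense genes x cells scaled matrix (see [scale_genes()]).
#' @param clusters cluster label per cell.
#' @param marker_table named list: type -> character vector of marker genes.
#' @return data.frame (`cluster`, `label`, `score`, `tie`).
#' @export
annotate_clusters <- function(scaled, clusters, marker_table) {
  stopifnot(length(clusters) == ncol(scaled))
  for (ty in names(marker_table)) {
    miss <- setdiff(marker_table[[ty]], rownames(scaled))
    if (length(miss)) stop("markers absent for type ", ty, ": ",
                           paste(miss, collapse = ", "))
    if (length(marker_table[[ty]]) == 0) stop("empty marker set: ", ty)
  }
  out <- lapply(split_in_order(seq_along(clusters), clusters),
    function(idx) {
      if (length(idx) == 0) stop("empty cluster")
      sc <- vapply(marker_table, function(gs)
        mean(scaled[gs, idx, drop = FALSE]), numeric(1))
      best <- which(sc == max(sc))
      data.frame(cluster = as.character(clusters[idx[1]]),
                 label = names(marker_table)[best[1]],
                 score = max(sc), tie = length(best) > 1,
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify cells into anterior/posterior compartments
#'
#' A cell is posterior iff the mean normalized expression of the posterior
#' markers strictly exceeds that of the anterior markers; ties (including
#' the all-zero case) go to anterior, the larger compartment whose marker
#' ci is near-ubiquitous.
#'
#' @param nm a `NormMatrix`.
#' @param posterior_genes posterior markers (default hh, en).
#' @param anterior_genes anterior markers (default ci).
#' @return named character vector `"anterior"`/`"posterior"` per cell.
#' @export
classify_compartment <- function(nm, posterior_genes = c("hh", "en"),
                                 anterior_genes = c("ci")) {
  miss <- setdiff(c(posterior_genes, anterior_genes), nm$gene_ids)
  if (length(miss)) stop("marker genes absent: ", paste(miss, collapse = ", "))
  post <- Matrix::colSums(nm$values[posterior_genes, , drop = FALSE]) /
    length(posterior_genes)
  ant <- Matrix::colSums(nm$values[anterior_genes, , drop = FALSE]) /
    length(anterior_genes)
  setNames(ifelse(post > ant, "posterior", "anterior"), nm$cell_ids)
}

#' Classify AMP clusters as direct or indirect
#'
#' Direct flight-muscle precursors express high Cut (ct) and low Vestigial
#' (vg); a cluster is direct iff its mean scaled ct strictly exceeds its
#' mean scaled vg, else indirect.
#'
#' @param scaled genes x cells scaled matrix over AMP cells.
#' @param clusters cluster label per cell (AMP clusters).
#' @param ct_gene,vg_gene marker gene ids.
#' @return data.frame (`cluster`, `amp_type`, `ct_mean`, `vg_mean`).
#' @export
classify_amp_type <- function(scaled, clusters, ct_gene = "ct",
                              vg_gene = "vg") {
  if (!ct_gene %in% rownames(scaled)) stop("missing gene: ", ct_gene)
  if (!vg_gene %in% rownames(scaled)) stop("missing gene: ", vg_gene)
  out <- lapply(split_in_order(seq_along(clusters), clusters),
    function(idx) {
      ctm <- mean(scaled[ct_gene, idx])
      vgm <- mean(scaled[vg_gene, idx])
      data.frame(cluster = as.character(clusters[idx[1]]),
                 amp_type = if (ctm > vgm) "direct" else "indirect",
                 ct_mean = ctm, vg_mean = vgm, stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
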