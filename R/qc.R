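#' Quality-control parameters
#'
#' Standard-deviation multipliers for the cluster-level and cell-level
#' filters, plus the marker sets used to recognise AMP-epithelium doublet
#' clusters.
#'
#' @param low_quality_sd a cluster is low quality when its mean nGene falls
#'   more than this many SDs below the global cell-level mean (default 1).
#' @param doublet_sd nGene elevation (in global SDs) required before a
#'   cluster is considered a doublet candidate (default 1).
#' @param subset_ngene_sd half-width, in subset SDs, of the retained nGene
#'   band within a layer subset (default 1.5).
#' @param subset_mito_sd mitochondrial-fraction cutoff, in subset SDs above
#'   the subset mean (default 1.5).
#' @param amp_markers,epi_markers marker genes identifying the two layers.
#' @param coexpr_fraction fraction of a cluster's cells that must be positive
#'   for at least one marker of *each* layer before the cluster is called a
#'   doublet cluster (default 0.5).
#' @return a `QCParams` list.
#' @export
qc_params <- function(low_quality_sd = 1.0, doublet_sd = 1.0,
                      subset_ngene_sd = 1.5, subset_mito_sd = 1.5,
                      amp_markers = c("SPARC", "twi"),
                      epi_markers = c("Fas3"),
                      coexpr_fraction = 0.5) {
  if (any(c(low_quality_sd, doublet_sd, subset_ngene_sd, subset_mito_sd) <= 0))
    stop("SD multipliers must be positive")
  structure(list(low_quality_sd = low_quality_sd, doublet_sd = doublet_sd,
                 subset_ngene_sd = subset_ngene_sd,
                 subset_mito_sd = subset_mito_sd,
                 amp_markers = amp_markers, epi_markers = epi_markers,
                 coexpr_fraction = coexpr_fraction),
            class = "QCParams")
}

.marker_positive_fraction <- function(nm, cells, markers) {
  present <- intersect(markers, nm$gene_ids)
  if (length(present) < length(markers))
    warning("marker gene(s) not found, skipped: ",
            paste(setdiff(markers, present), collapse = ", "))
  if (length(present) == 0)
    stop("no marker of the set {", paste(markers, collapse = ", "),
         "} is present")
  v <- nm$values[present, cells, drop = FALSE]
  mean(Matrix::colSums(v > 0) > 0)
}

#' Flag low-quality and suspected-doublet clusters
#'
#' A cluster is `low_quality` when its mean nGene is more than
#' `low_quality_sd` global standard deviations below the cell-level mean
#' nGene of the whole dataset.  A cluster is a `suspected_doublet` when its
#' mean nGene exceeds the global mean by more than `doublet_sd` SDs *and*
#' the cluster co-expresses the marker sets of both tissue layers (at least
#' `coexpr_fraction` of its cells positive for each set).  All statistics
#' use the sample (n - 1) standard deviation over individual cells.
#'
#' @param stats a `CellStats` table (see [compute_cell_stats()]).
#' @param nm the `NormMatrix` of the same cells (marker positivity is read
#'   from normalized values > 0).
#' @param clusters cluster label per cell (same order as `stats`).
#' @param params a [qc_params()] object.
#' @return data.frame with one row per cluster: `cluster`, `n_cells`,
#'   `mean_ngene`, `low_quality`, `suspected_doublet`, `keep`.
#' @export
flag_clusters <- function(stats, nm, clusters, params = qc_params()) {
  if (length(clusters) != nrow(stats))
    stop("every cell needs a cluster label")
  if (anyNA(clusters)) stop("every cell needs a cluster label")
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2) stop("need at least 2 clusters")
  mu <- mean(stats$n_gene)
  sdv <- stats::sd(stats$n_gene)
  out <- do.call(rbind, lapply(split_in_order(seq_along(clusters), clusters),
    function(idx) {
      m <- mean(stats$n_gene[idx])
      low <- m < mu - params$low_quality_sd * sdv
      doub <- FALSE
      if (m > mu + params$doublet_sd * sdv) {
        cells <- stats$cell_id[idx]
        fa <- .marker_positive_fraction(nm, cells, params$amp_markers)
        fe <- .marker_positive_fraction(nm, cells, params$epi_markers)
        doub <- fa >= params$coexpr_fraction && fe >= params$coexpr_fraction
      }
      data.frame(cluster = clusters[idx[1]], n_cells = length(idx),
                 mean_ngene = m, low_quality = low,
                 suspected_doublet = doub, keep = !(low || doub),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Filter cells within a layer subset by nGene and mitochondrial fraction
#'
#' Removes cells whose nGene lies strictly outside the subset mean +/- 1.5
#' subset SDs, and cells whose mitochondrial fraction is strictly greater
#' than the subset mean + 1.5 subset SDs.  Both statistics are computed once
#' on the pristine subset and applied jointly in one pass; boundary cells
#' are retained.
#'
#' @param stats a `CellStats` table covering (at least) the subset.
#' @param subset_cell_ids cell ids of the subset to filter.
#' @param params a [qc_params()] object.
#' @return list with `retained` (cell ids), and a per-cell `report`
#'   data.frame with reason codes (`ngene_low`, `ngene_high`, `mito_high`).
#' @export
filter_cells_within_subset <- function(stats, subset_cell_ids,
                                       params = qc_params()) {
  idx <- match(subset_cell_ids, stats$cell_id)
  if (anyNA(idx)) stop("unknown cell ids in subset")
  if (length(idx) < 3) stop("subset needs at least 3 cells")
  ng <- stats$n_gene[idx]
  pm <- stats$pct_mito[idx]
  ng_mu <- mean(ng); ng_sd <- stats::sd(ng)
  pm_mu <- mean(pm); pm_sd <- stats::sd(pm)
  lo <- ng < ng_mu - params$subset_ngene_sd * ng_sd
  hi <- ng > ng_mu + params$subset_ngene_sd * ng_sd
  mh <- pm > pm_mu + params$subset_mito_sd * pm_sd
  reason <- ifelse(lo, "ngene_low",
                   ifelse(hi, "ngene_high", ifelse(mh, "mito_high", "")))
  keep <- !(lo | hi | mh)
  list(retained = subset_cell_ids[keep],
       report = data.frame(cell_id = subset_cell_ids, retained = keep,
                           reason = reason, stringsAsFactors = FALSE))
}
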