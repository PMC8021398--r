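#' Construct/validate a pathway table
#'
#' @param df data.frame with columns `pathway`, `gene`,
#'   `role` (`"ligand"` or `"receptor"`).
#' @return a `PathwayTable` data.frame.
#' @export
pathway_table <- function(df) {
  need <- c("pathway", "gene", "role")
  if (!all(need %in% names(df)))
    stop("pathway table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$role %in% c("ligand", "receptor")))
    stop("role must be 'ligand' or 'receptor'")
  if (anyDuplicated(df[, need]))
    stop("duplicate (pathway, gene, role) rows")
  df <- df[, need]
  class(df) <- c("PathwayTable", "data.frame")
  df
}

#' Read a pathway CSV (pathway, gene, role)
#' @param path CSV path.
#' @return a `PathwayTable`.
#' @export
read_pathway_table <- function(path) {
  pathway_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Screen signaling pathways for differential receptor/ligand expression
#'
#' A pathway is retained when at least one of its ligand or receptor genes
#' is significantly differentially expressed (three-part criterion) in any
#' of three contexts: (1) one epithelial domain (notum, hinge, pouch, PE)
#' vs all other epithelial cells; (2) direct vs indirect AMPs, compared to
#' each other; (3) all epithelial cells vs all AMP cells.  The triggering
#' context and gene are recorded per retained pathway.
#'
#' @param nm a `NormMatrix`.
#' @param annotations data.frame over the same cells with columns `layer`
#'   (`"AMP"`/`"epithelium"`), `domain` (epithelial domain labels) and
#'   `amp_type` (`"direct"`/`"indirect"`).
#' @param pathways a `PathwayTable`; genes absent from the matrix are
#'   skipped with a warning.
#' @param thr a [de_thresholds()] object.
#' @return a `ScreenResult`: list with `retained` (pathway names), `hits`
#'   (data.frame pathway/gene/role/context/lnfc/fdr) and `tables` (the
#'   per-context `DETable`s restricted to pathway genes).
#' @export
screen_pathways <- function(nm, annotations, pathways,
                            thr = de_thresholds()) {
  stopifnot(nrow(annotations) == length(nm$cell_ids))
  present <- pathways$gene %in% nm$gene_ids
  if (any(!present))
    warning("pathway genes absent, skipped: ",
            paste(unique(pathways$gene[!present]), collapse = ", "))
  pw <- pathways[present, , drop = FALSE]
  if (nrow(pw) == 0)
    return(structure(list(retained = character(0),
                          hits = data.frame(), tables = list()),
                     class = "ScreenResult"))
  ids <- nm$cell_ids
  epi <- which(annotations$layer == "epithelium")
  amp <- which(annotations$layer == "AMP")
  tables <- list()
  # context 1: each epithelial domain vs all other epithelial cells
  for (dom in unique(stats::na.omit(annotations$domain[epi]))) {
    a <- ids[epi][annotations$domain[epi] == dom]
    b <- ids[epi][annotations$domain[epi] != dom]
    if (length(a) >= 3 && length(b) >= 3)
      tables[[paste0("epithelium_domain:", dom)]] <- wilcoxon_de(nm, a, b)
  }
  # context 2: direct vs indirect AMPs
  a <- ids[amp][annotations$amp_type[amp] %in% "direct"]
  b <- ids[amp][annotations$amp_type[amp] %in% "indirect"]
  if (length(a) >= 3 && length(b) >= 3)
    tables[["amp_subtype:direct_vs_indirect"]] <- wilcoxon_de(nm, a, b)
  # context 3: all epithelium vs all AMPs
  if (length(epi) >= 3 && length(amp) >= 3)
    tables[["layer:epithelium_vs_AMP"]] <- wilcoxon_de(nm, ids[epi],
                                                       ids[amp])
  hits <- do.call(rbind, lapply(names(tables), function(ctx) {
    sig <- call_significant(tables[[ctx]], thr)
    sig <- sig[sig$gene %in% pw$gene, , drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    m <- merge(pw, sig[, c("gene", "lnfc", "fdr")], by = "gene")
    m$context <- ctx
    m
  }))
  if (is.null(hits)) hits <- data.frame(pathway = character(0))
  retained <- sort_c(unique(hits$pathway))
  structure(list(retained = retained, hits = hits, tables = tables),
            class = "ScreenResult")
}

#' Dot-plot statistics per (group, gene)
#'
#' Dot size: fraction of the group's cells with normalized value > 0.
#' Dot color: the group's mean scaled (z-scored) expression.
#'
#' @param nm a `NormMatrix`.
#' @param scaled matching genes x cells scaled matrix.
#' @param groups group label per cell.
#' @param genes genes to tabulate.
#' @return data.frame (`group`, `gene`, `pct_expressing`,
#'   `mean_scaled_expression`).
#' @export
dotplot_stats <- function(nm, scaled, groups, genes) {
  miss <- setdiff(genes, nm$gene_ids)
  if (length(miss)) stop("genes absent: ", paste(miss, collapse = ", "))
  idx_by_group <- split_in_order(seq_along(groups), groups)
  out <- do.call(rbind, lapply(names(idx_by_group), function(g) {
    idx <- idx_by_group[[g]]
    if (length(idx) == 0) stop("empty group: ", g)
    data.frame(group = g, gene = genes,
               pct_expressing =
                 Matrix::rowSums(nm$values[genes, idx, drop = FALSE] > 0) /
                 length(idx),
               mean_scaled_expression =
                 rowMeans(scaled[genes, idx, drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-layer ligand-receptor complementarity calls
#'
#' Emits a call whenever a retained pathway's ligand is expressed (percent
#' of expressing cells at least `pct_min`) in an epithelial group while its
#' receptor is expressed in an AMP group, or vice versa.  Calls are
#' presence-based, not significance-based.
#'
#' @param screen a `ScreenResult` from [screen_pathways()].
#' @param dots a [dotplot_stats()] table whose groups are tagged by layer
#'   via `group_layers`.
#' @param group_layers named character vector mapping each group to
#'   `"epithelium"` or `"AMP"`.
#' @param pathways the `PathwayTable` used in the screen.
#' @param pct_min expression threshold (default 0.15).
#' @return data.frame of calls: `pathway`, `ligand`, `ligand_group`,
#'   `receptor`, `receptor_group`.
#' @export
complementarity_calls <- function(screen, dots, group_layers, pathways,
                                  pct_min = 0.15) {
  calls <- list()
  for (pwn in screen$retained) {
    lig <- pathways$gene[pathways$pathway == pwn &
                           pathways$role == "ligand"]
    rec <- pathways$gene[pathways$pathway == pwn &
                           pathways$role == "receptor"]
    for (lg in lig) for (rg in rec) {
      ld <- dots[dots$gene == lg & dots$pct_expressing >= pct_min, ]
      rd <- dots[dots$gene == rg & dots$pct_expressing >= pct_min, ]
      if (nrow(ld) == 0 || nrow(rd) == 0) next
      for (i in seq_len(nrow(ld))) for (j in seq_len(nrow(rd))) {
        l_layer <- group_layers[[ld$group[i]]]
        r_layer <- group_layers[[rd$group[j]]]
        if (is.null(l_layer) || is.null(r_layer)) next
        if (l_layer != r_layer)
          calls[[length(calls) + 1L]] <- data.frame(
            pathway = pwn, ligand = lg, ligand_group = ld$group[i],
            receptor = rg, receptor_group = rd$group[j],
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0)
    return(data.frame(pathway = character(0), ligand = character(0),
                      ligand_group = character(0), receptor = character(0),
                      receptor_group = character(0)))
  unique(do.call(rbind, calls))
}
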