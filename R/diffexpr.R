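#' Significance thresholds for differential expression
#'
#' The three-part criterion: FDR strictly below `fdr_max`, absolute
#' natural-log fold-change of `lnfc_min` or more, and at least `pct_min`
#' of cells expressing the gene in one of the two populations.
#'
#' @param fdr_max FDR cutoff, strict (default 0.05).
#' @param lnfc_min minimum |lnFC|, inclusive (default 0.15).
#' @param pct_min minimum percent-expressing in either group, inclusive
#'   (default 0.15).
#' @return a `DEThresholds` list.
#' @export
de_thresholds <- function(fdr_max = 0.05, lnfc_min = 0.15, pct_min = 0.15) {
  stopifnot(fdr_max > 0, fdr_max <= 1, lnfc_min >= 0,
            pct_min >= 0, pct_min <= 1)
  structure(list(fdr_max = fdr_max, lnfc_min = lnfc_min, pct_min = pct_min),
            class = "DEThresholds")
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene: a two-sided rank-sum test on natural-log normalized values
#' (exact tail probabilities when the pooled sample is at most 10 cells
#' with no ties; otherwise the normal approximation with tie and continuity
#' correction), the natural-log fold-change
#' `ln((mean(expm1(A)) + 1) / (mean(expm1(B)) + 1))`, the fraction of
#' expressing cells per group, and Benjamini-Hochberg FDR over the tested
#' genes.
#'
#' @param nm a `NormMatrix`.
#' @param group_a_ids,group_b_ids disjoint cell-id vectors, each with at
#'   least 3 cells.
#' @param genes optional gene subset to test (default: all genes).
#' @return a `DETable` data.frame: `gene`, `stat` (Mann-Whitney U of group
#'   A), `p`, `fdr`, `lnfc`, `pct_a`, `pct_b`.
#' @export
wilcoxon_de <- function(nm, group_a_ids, group_b_ids, genes = NULL) {
  if (length(intersect(group_a_ids, group_b_ids)) > 0)
    stop("groups overlap")
  if (length(group_a_ids) < 3 || length(group_b_ids) < 3)
    stop("each group needs at least 3 cells")
  ia <- match(group_a_ids, nm$cell_ids)
  ib <- match(group_b_ids, nm$cell_ids)
  if (anyNA(ia) || anyNA(ib)) stop("unknown cell ids")
  gi <- if (is.null(genes)) seq_along(nm$gene_ids) else
    match(genes, nm$gene_ids)
  if (anyNA(gi)) stop("unknown genes")
  x <- as.matrix(nm$values[gi, c(ia, ib), drop = FALSE])
  na <- length(ia); nb <- length(ib); n <- na + nb
  rk <- matrix(0, nrow(x), n)
  tie_term <- numeric(nrow(x))
  has_ties <- logical(nrow(x))
  for (g in seq_len(nrow(x))) {
    r <- rank(x[g, ])
    rk[g, ] <- r
    tt <- tabulate(match(x[g, ], unique(x[g, ])))
    tie_term[g] <- sum(tt^3 - tt)
    has_ties[g] <- any(tt > 1)
  }
  u <- rowSums(rk[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- ifelse(sigma2 > 0, pmin(1, 2 * stats::pnorm(-abs(z))), 1)
  if (n <= 10) {
    exact <- which(!has_ties)
    for (g in exact) {
      pg <- if (u[g] > mu) 1 - stats::pwilcox(u[g] - 1, na, nb) else
        stats::pwilcox(u[g], na, nb)
      p[g] <- min(1, 2 * pg)
    }
  }
  ea <- expm1(x[, seq_len(na), drop = FALSE])
  eb <- expm1(x[, na + seq_len(nb), drop = FALSE])
  lnfc <- log(rowMeans(ea) + 1) - log(rowMeans(eb) + 1)
  out <- data.frame(gene = nm$gene_ids[gi], stat = u, p = p,
                    fdr = bh_adjust(p), lnfc = lnfc,
                    pct_a = rowMeans(x[, seq_len(na), drop = FALSE] > 0),
                    pct_b = rowMeans(x[, na + seq_len(nb), drop = FALSE] > 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DETable", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, take running minima of `p * m / rank`
#' from the largest rank down, cap at 1, return in input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return FDR values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the three-part significance criterion
#'
#' @param table a `DETable`.
#' @param thr a [de_thresholds()] object.
#' @return the rows of `table` passing `fdr < fdr_max`,
#'   `|lnfc| >= lnfc_min` and `max(pct_a, pct_b) >= pct_min`.
#' @export
call_significant <- function(table, thr = de_thresholds()) {
  keep <- table$fdr < thr$fdr_max &
    abs(table$lnfc) >= thr$lnfc_min &
    pmax(table$pct_a, table$pct_b) >= thr$pct_min
  table[keep, , drop = FALSE]
}

#' One-cluster-vs-all marker detection
#'
#' For each cluster, tests the cluster against the complement and applies
#' the three-part criterion; BH is applied within each comparison over all
#' tested genes.
#'
#' @param nm a `NormMatrix`.
#' @param clusters cluster label per cell.
#' @param thr a [de_thresholds()] object.
#' @return named list per cluster: `table` (full `DETable`) and
#'   `significant` (filtered rows).  Clusters too small to test are skipped
#'   with a warning.
#' @export
one_vs_all_markers <- function(nm, clusters, thr = de_thresholds()) {
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2) stop("need at least 2 clusters")
  out <- list()
  for (cl in unique(clusters)) {
    a <- nm$cell_ids[clusters == cl]
    b <- nm$cell_ids[clusters != cl]
    if (length(a) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    tab <- wilcoxon_de(nm, a, b)
    out[[cl]] <- list(table = tab, significant = call_significant(tab, thr))
  }
  out
}

#' Temporally consistent differential expression
#'
#' Time-point contrasts are confounded with batch, so a gene is reported
#' only when it is significant (three-part criterion) with a consistent
#' fold-change sign in *every* (early-batch, late-batch) pairwise
#' comparison (4 pairs for a 2x2 design).  Reported effect size is the
#' natural log of the arithmetic mean of the per-pair linear fold-change
#' ratios (or the mean of the lnFCs with `average = "log"`), alongside the
#' maximum FDR over the pairs.
#'
#' @param nm a `NormMatrix`.
#' @param group_ids cells to compare across time (e.g., one cell type).
#' @param thr a [de_thresholds()] object.
#' @param average `"linear"` (default): ln(mean of linear ratios);
#'   `"log"`: mean of per-pair lnFCs.
#' @param time_order optional length-2 character vector giving the early and
#'   late time labels in order; by default labels are ordered by their
#'   leading number (so `"96h"` precedes `"120h"`), falling back to
#'   alphabetical order.
#' @param require_consistent_sign drop genes whose lnFC changes sign across
#'   pairs (default `TRUE`).
#' @return list with `table` (gene, ln_avg_fc, max_fdr, n_pairs) over the
#'   consistently significant genes, and `pairs`, the per-pair `DETable`s.
#' @export
temporal_consistent_de <- function(nm, group_ids, thr = de_thresholds(),
                                   average = c("linear", "log"),
                                   require_consistent_sign = TRUE,
                                   time_order = NULL) {
  average <- match.arg(average)
  meta <- nm$cell_meta[match(group_ids, nm$cell_ids), , drop = FALSE]
  if (anyNA(meta$time)) stop("cells need time labels")
  times <- unique(meta$time)
  if (length(times) != 2) stop("need exactly 2 time points")
  if (!is.null(time_order)) {
    if (!setequal(time_order, times)) stop("time_order must name both times")
    times <- time_order
  } else {
    num <- suppressWarnings(as.numeric(sub("[^0-9.].*$", "", times)))
    times <- if (!anyNA(num)) times[order(num)] else sort(times)
  }
  early_batches <- unique(meta$batch[meta$time == times[1]])
  late_batches <- unique(meta$batch[meta$time == times[2]])
  pairs <- expand.grid(early = early_batches, late = late_batches,
                       stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- group_ids[meta$batch == pairs$early[i]]
    b <- group_ids[meta$batch == pairs$late[i]]
    if (length(a) < 3 || length(b) < 3)
      stop("group absent (or too small) in batch pair ",
           pairs$early[i], " vs ", pairs$late[i])
    wilcoxon_de(nm, a, b)
  })
  names(tabs) <- paste(pairs$early, pairs$late, sep = "_vs_")
  sig_sets <- lapply(tabs, function(t) call_significant(t, thr)$gene)
  consistent <- Reduce(intersect, sig_sets)
  if (length(consistent) > 0) {
    lnfc_mat <- vapply(tabs, function(t)
      t$lnfc[match(consistent, t$gene)], numeric(length(consistent)))
    lnfc_mat <- matrix(lnfc_mat, nrow = length(consistent))
    if (require_consistent_sign) {
      same_sign <- apply(lnfc_mat, 1, function(v)
        all(v > 0) || all(v < 0))
      consistent <- consistent[same_sign]
      lnfc_mat <- lnfc_mat[same_sign, , drop = FALSE]
    }
  }
  if (length(consistent) == 0) {
    table <- data.frame(gene = character(0), ln_avg_fc = numeric(0),
                        max_fdr = numeric(0), n_pairs = integer(0))
  } else {
    ln_avg <- if (average == "linear")
      log(rowMeans(exp(lnfc_mat))) else rowMeans(lnfc_mat)
    fdr_mat <- vapply(tabs, function(t)
      t$fdr[match(consistent, t$gene)], numeric(length(consistent)))
    fdr_mat <- matrix(fdr_mat, nrow = length(consistent))
    table <- data.frame(gene = consistent, ln_avg_fc = ln_avg,
                        max_fdr = apply(fdr_mat, 1, max),
                        n_pairs = nrow(pairs), stringsAsFactors = FALSE)
  }
  list(table = table, pairs = tabs)
}
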