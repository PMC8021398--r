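#' Configuration for the synthetic wing-disc simulator
#'
#' Defines the study conditions the simulator emulates: a two-layer tissue
#' (columnar/peripodial epithelium plus adherent adult muscle precursors,
#' AMPs) sampled at two larval time points with two replicates each,
#' male/female dosage-compensation bimodality, an S-phase cell-cycle program,
#' AMP-epithelium doublets, and a direct/indirect AMP divergence that is
#' strong late and weak or absent early.
#'
#' Counts are negative binomial around a product of a gene baseline, planted
#' program fold-changes, a per-batch lognormal factor and a per-cell
#' lognormal library size.
#'
#' @param n_cells_per_batch cells simulated per batch.
#' @param batches data.frame with columns `label` and `time`.
#' @param amp_fraction fraction of cells in the AMP layer.
#' @param pe_fraction fraction of epithelial cells in the peripodial layer.
#' @param domain_breaks named fractions of the proximodistal axis occupied by
#'   notum, hinge and pouch (must sum to 1).
#' @param posterior_fraction fraction of the tissue posterior to the A/P
#'   boundary.
#' @param male_fraction probability a cell is male.
#' @param doublet_rate fraction of barcodes that are AMP-epithelium doublets
#'   (exactly `floor(rate * n)` per batch).
#' @param direct_fraction fraction of AMPs on the direct (DFM) lineage.
#' @param cell_cycle_fraction fraction of cells in the S-like phase.
#' @param divergence_at_96h if `TRUE` the direct/indirect programs already
#'   differ (weakly) at the early time point; default `FALSE` - they only
#'   diverge at 120h.
#' @param marker_fc linear fold-change of landmark genes in cells whose
#'   reference position carries the pattern (in situ-grade on/off markers).
#' @param domain_fc,compartment_fc,layer_fc,subtype_fc,weak_subtype_fc,cc_fc,temporal_fc,pathway_fc
#'   linear fold-changes of the respective planted gene programs.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param lib_meanlog,lib_sdlog lognormal library-size parameters.
#' @param batch_scale sdlog of the per-batch per-gene lognormal factor
#'   (0 disables batch effects).
#' @param n_background number of unstructured background genes.
#' @param nx,ny reference grid resolution (proximodistal x, A/P y).
#' @param amp_nx AMP-layer grid columns (AMP layer spans the notum region).
#' @param stripe_x,stripe_y number of x/y stripe landmark genes; evenly
#'   spaced thresholds.  Defaults align with the grid so every position is
#'   identifiable.
#' @param identifiable if `TRUE`, `simulate_reference` errors when two
#'   same-layer positions share a landmark pattern.
#' @param seed integer seed; all draws flow from one generator.
#' @return a validated `DiscSimConfig` list.
#' @export
disc_sim_config <- function(n_cells_per_batch = 1250,
                            batches = data.frame(
                              label = c("96h_r1", "96h_r2", "120h_r1", "120h_r2"),
                              time = c("96h", "96h", "120h", "120h"),
                              stringsAsFactors = FALSE),
                            amp_fraction = 0.6,
                            pe_fraction = 0.15,
                            domain_breaks = c(notum = 0.35, hinge = 0.30, pouch = 0.35),
                            posterior_fraction = 0.5,
                            male_fraction = 0.4,
                            doublet_rate = 0.05,
                            direct_fraction = 0.25,
                            cell_cycle_fraction = 0.5,
                            divergence_at_96h = FALSE,
                            marker_fc = 10,
                            domain_fc = 3,
                            compartment_fc = 4,
                            layer_fc = 3,
                            subtype_fc = 6,
                            weak_subtype_fc = 1.5,
                            cc_fc = 4,
                            temporal_fc = 2,
                            pathway_fc = 6,
                            dispersion = 0.15,
                            lib_meanlog = log(1500),
                            lib_sdlog = 0.3,
                            batch_scale = 0.1,
                            n_background = 1200,
                            nx = 10, ny = 5, amp_nx = 4,
                            stripe_x = nx - 1, stripe_y = ny - 1,
                            identifiable = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(amp_fraction, pe_fraction, posterior_fraction, male_fraction,
          direct_fraction, cell_cycle_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (doublet_rate < 0 || doublet_rate > 0.5)
    stop("doublet_rate must lie in [0, 0.5]")
  if (abs(sum(domain_breaks) - 1) > 1e-8)
    stop("domain_breaks must sum to 1")
  fc <- c(marker_fc, domain_fc, compartment_fc, layer_fc, subtype_fc,
          weak_subtype_fc, cc_fc, temporal_fc, pathway_fc)
  if (any(fc <= 0)) stop("effect sizes must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (!all(c("label", "time") %in% names(batches)))
    stop("batches needs label and time columns")
  class(cfg) <- "DiscSimConfig"
  cfg
}

# position table helpers --------------------------------------------------

.domain_of_x <- function(x, breaks) {
  as.character(cut(x, breaks = c(-Inf, cumsum(breaks)[1:2], Inf),
                   labels = names(breaks)))
}

#' Simulate the three-layered binarized spatial reference
#'
#' Builds a grid of positions across the three tissue layers (AMP layer
#' restricted to the notum-adjacent region, disc proper covering all
#' proximodistal domains, peripodial epithelium as an outline) and a binary
#' landmark-gene x position pattern matrix: layer markers, domain markers,
#' anterior/posterior compartment markers, and stripe landmarks encoding
#' the x/y coordinate so each position is identifiable within its layer.
#' The construction is deterministic (no random draws).
#'
#' @param config a [disc_sim_config()].
#' @return a `LayeredReference`: `positions` data.frame (id, layer, x, y,
#'   plus annotation columns domain and compartment) and binary `patterns`
#'   (landmark genes x positions).
#' @export
simulate_reference <- function(config = disc_sim_config()) {
  nx <- config$nx; ny <- config$ny
  xs <- (seq_len(nx) - 0.5) / nx
  ys <- (seq_len(ny) - 0.5) / ny
  dp <- expand.grid(xi = seq_len(nx), yi = seq_len(ny))
  dp_pos <- data.frame(id = sprintf("DP_%02d_%02d", dp$xi, dp$yi),
                       layer = "DP", x = xs[dp$xi], y = ys[dp$yi],
                       stringsAsFactors = FALSE)
  notum_span <- unname(config$domain_breaks["notum"])
  amp_xs <- notum_span * (seq_len(config$amp_nx) - 0.5) / config$amp_nx
  am <- expand.grid(xi = seq_len(config$amp_nx), yi = seq_len(ny))
  amp_pos <- data.frame(id = sprintf("AMP_%02d_%02d", am$xi, am$yi),
                        layer = "AMP", x = amp_xs[am$xi], y = ys[am$yi],
                        stringsAsFactors = FALSE)
  # PE as a squamous outline: one row of large positions above and below
  pe_pos <- rbind(
    data.frame(id = sprintf("PE_t_%02d", seq_len(nx)), layer = "PE",
               x = xs, y = 1.04, stringsAsFactors = FALSE),
    data.frame(id = sprintf("PE_b_%02d", seq_len(nx)), layer = "PE",
               x = xs, y = -0.04, stringsAsFactors = FALSE))
  pos <- rbind(amp_pos, dp_pos, pe_pos)
  pos$domain <- ifelse(pos$layer == "DP",
                       .domain_of_x(pos$x, config$domain_breaks),
                       ifelse(pos$layer == "PE", "PE", "AMP"))
  pos$compartment <- ifelse(pos$y > config$posterior_fraction,
                            "posterior", "anterior")

  pat <- function(keep) as.integer(keep)
  tx <- seq_len(config$stripe_x) / (config$stripe_x + 1)
  ty <- seq_len(config$stripe_y) / (config$stripe_y + 1)
  rows <- list(
    SPARC = pat(pos$layer == "AMP"),
    twi   = pat(pos$layer == "AMP"),
    Fas3  = pat(pos$layer %in% c("DP", "PE")),
    Ubx   = pat(pos$layer == "PE"),
    pnr   = pat(pos$layer == "DP" & pos$domain == "notum"),
    zfh2  = pat(pos$layer == "DP" & pos$domain == "hinge"),
    nub   = pat(pos$layer == "DP" & pos$domain == "pouch"),
    en    = pat(pos$compartment == "posterior"),
    hh    = pat(pos$compartment == "posterior"),
    ci    = pat(pos$compartment == "anterior"))
  for (k in seq_along(tx)) rows[[sprintf("lmx%02d", k)]] <- pat(pos$x > tx[k])
  for (k in seq_along(ty)) rows[[sprintf("lmy%02d", k)]] <- pat(pos$y > ty[k])
  patterns <- do.call(rbind, rows)
  colnames(patterns) <- pos$id
  ref <- layered_reference(pos, patterns)
  if (isTRUE(config$identifiable)) {
    for (ly in unique(pos$layer)) {
      cols <- patterns[, pos$layer == ly, drop = FALSE]
      if (anyDuplicated(t(cols)))
        stop("landmark set too small: duplicate patterns within layer ", ly,
             " (increase stripe_x/stripe_y)")
    }
  }
  ref
}

# gene table: id, class (for truth bookkeeping), baseline weight -----------
.disc_gene_table <- function(config) {
  g <- function(id, class, base) data.frame(gene = id, class = class,
                                            base = base,
                                            stringsAsFactors = FALSE)
  lm_ids <- c("SPARC", "twi", "Fas3", "Ubx", "pnr", "zfh2", "nub",
              "en", "hh", "ci",
              sprintf("lmx%02d", seq_len(config$stripe_x)),
              sprintf("lmy%02d", seq_len(config$stripe_y)))
  rbind(
    g(lm_ids, "landmark", 0.4),
    g(c("roX1", "roX2"), "sex", 0.02),
    g(c("ct"), "direct_tf", 0.5),
    g(c("vg"), "indirect_tf", 0.5),
    g(sprintf("cc_%02d", 1:10), "cell_cycle", 1.0),
    g(c("PCNA", "CycB"), "cell_cycle", 1.0),
    g(sprintf("mt:%s", c("CoI", "CoII", "CoIII", "ND1", "ATPase6")),
      "mito", 8),
    g(sprintf("prog_notum_%02d", 1:10), "notum_program", 0.8),
    g(sprintf("prog_hinge_%02d", 1:10), "hinge_program", 0.8),
    g(sprintf("prog_pouch_%02d", 1:10), "pouch_program", 0.8),
    g(sprintf("prog_pe_%02d", 1:10), "pe_program", 0.8),
    g(sprintf("prog_post_%02d", 1:8), "posterior_program", 0.8),
    g(sprintf("prog_amp_%03d", 1:120), "amp_program", 0.8),
    g(sprintf("prog_epi_%03d", 1:120), "epi_program", 0.8),
    g(sprintf("prog_direct_%02d", 1:40), "direct_program", 0.5),
    g(sprintf("prog_indirect_%02d", 1:40), "indirect_program", 0.5),
    g(sprintf("tmp_up_%02d", 1:10), "late_up", 0.8),
    g(sprintf("tmp_dn_%02d", 1:10), "late_down", 0.8),
    g(sprintf("art_%02d", 1:5), "batch_artifact", 0.8),
    g(c("ths", "pyr"), "fgf_ligand", 0.2),
    g("htl", "fgf_receptor", 0.2),
    g("ptc", "hh_receptor", 0.2),
    g("smo", "hh_receptor2", 0.5),
    g(c("wg", "fz", "N", "Dl"), "uniform_pathway", 0.8),
    g(sprintf("bg_%04d", seq_len(config$n_background)), "background", NA))
}

#' The pathway table bundled with the simulator
#'
#' Ligand/receptor roles for the pathways planted in (or deliberately left
#' uniform in) the synthetic disc: FGF (ths/pyr -> htl), Hedgehog
#' (hh -> ptc, smo), Wnt/Wingless and Notch (uniform, so a correct screen
#' drops them).
#'
#' @return a `PathwayTable` data.frame (pathway, gene, role).
#' @export
disc_sim_pathways <- function() {
  pathway_table(data.frame(
    pathway = c("FGF", "FGF", "FGF", "Hedgehog", "Hedgehog", "Hedgehog",
                "Wnt/Wingless", "Wnt/Wingless", "Notch", "Notch"),
    gene = c("ths", "pyr", "htl", "hh", "ptc", "smo",
             "wg", "fz", "Dl", "N"),
    role = c("ligand", "ligand", "receptor", "ligand", "receptor", "receptor",
             "ligand", "receptor", "ligand", "receptor"),
    stringsAsFactors = FALSE))
}

# attribute draw for one batch of single cells
.draw_cell_attrs <- function(n, config, ref, time) {
  pos <- ref$positions
  layer <- ifelse(runif(n) < config$amp_fraction, "AMP", "epithelium")
  pos_id <- character(n)
  is_amp <- layer == "AMP"
  amp_ids <- pos$id[pos$layer == "AMP"]
  dp_ids <- pos$id[pos$layer == "DP"]
  pe_ids <- pos$id[pos$layer == "PE"]
  pos_id[is_amp] <- sample(amp_ids, sum(is_amp), replace = TRUE)
  n_epi <- sum(!is_amp)
  in_pe <- runif(n_epi) < config$pe_fraction
  epi_pos <- character(n_epi)
  epi_pos[in_pe] <- sample(pe_ids, sum(in_pe), replace = TRUE)
  epi_pos[!in_pe] <- sample(dp_ids, sum(!in_pe), replace = TRUE)
  pos_id[!is_amp] <- epi_pos
  pidx <- match(pos_id, pos$id)
  data.frame(
    layer = layer,
    position = pos_id,
    domain = pos$domain[pidx],
    compartment = pos$compartment[pidx],
    sex = ifelse(runif(n) < config$male_fraction, "male", "female"),
    phase = ifelse(runif(n) < config$cell_cycle_fraction, "S", "non-S"),
    amp_type = ifelse(is_amp,
                      ifelse(runif(n) < config$direct_fraction,
                             "direct", "indirect"),
                      NA_character_),
    time = time,
    stringsAsFactors = FALSE)
}

# genes x cells multiplier matrix from planted programs
.effect_matrix <- function(genes, attrs, config, ref) {
  n <- nrow(attrs)
  eff <- matrix(1, nrow(genes), n, dimnames = list(genes$gene, NULL))
  cls <- genes$class
  pidx <- match(attrs$position, ref$positions$id)
  lm <- which(cls == "landmark")
  onpat <- ref$patterns[genes$gene[lm], pidx, drop = FALSE]
  eff[lm, ] <- 1 + (config$marker_fc - 1) * onpat
  mul <- function(rows, cells, fc) {
    if (any(cells)) eff[rows, cells] <<- eff[rows, cells] * fc
  }
  epi <- attrs$layer == "epithelium"
  amp <- attrs$layer == "AMP"
  late <- attrs$time == "120h"
  sub_fc <- ifelse(late, config$subtype_fc,
                   if (config$divergence_at_96h) config$weak_subtype_fc else 1)
  mul(cls == "sex", attrs$sex == "male", 600)  # roX on/off: male-exclusive
  mul(cls == "cell_cycle", attrs$phase == "S", config$cc_fc)
  mul(cls == "notum_program", epi & attrs$domain == "notum", config$domain_fc)
  mul(cls == "hinge_program", epi & attrs$domain == "hinge", config$domain_fc)
  mul(cls == "pouch_program", epi & attrs$domain == "pouch", config$domain_fc)
  mul(cls == "pe_program", epi & attrs$domain == "PE", config$domain_fc)
  mul(cls == "posterior_program", attrs$compartment == "posterior",
      config$compartment_fc)
  mul(cls == "amp_program", amp, config$layer_fc)
  mul(cls == "epi_program", epi, config$layer_fc)
  dirc <- which(amp & attrs$amp_type == "direct")
  indc <- which(amp & attrs$amp_type == "indirect")
  dr <- cls %in% c("direct_program", "direct_tf")
  ir <- cls %in% c("indirect_program", "indirect_tf")
  if (length(dirc))
    eff[dr, dirc] <- eff[dr, dirc] *
      rep(sub_fc[dirc], each = sum(dr))
  if (length(indc))
    eff[ir, indc] <- eff[ir, indc] *
      rep(sub_fc[indc], each = sum(ir))
  mul(cls == "late_up", late, config$temporal_fc)
  mul(cls == "late_down", !late, config$temporal_fc)
  mul(cls == "fgf_ligand", epi & attrs$domain == "notum", config$pathway_fc)
  mul(cls == "fgf_receptor", amp, config$pathway_fc)
  mul(cls == "hh_receptor", amp & attrs$compartment == "posterior",
      config$pathway_fc)
  mul(cls == "hh_receptor2", amp, config$layer_fc)
  eff
}

#' Simulate a multi-batch synthetic wing disc with planted ground truth
#'
#' Draws every batch's counts from the negative-binomial model described in
#' [disc_sim_config()], plants doublets by summing the counts of one random
#' epithelial and one random AMP cell, and returns full per-cell and
#' per-gene truth tables alongside the matching spatial reference.
#'
#' @param config a [disc_sim_config()].
#' @return list with elements `counts` (a `CountMatrix` over all batches),
#'   `truth` (per-cell data.frame: layer, domain, compartment, sex, phase,
#'   amp_type, doublet, position), `gene_truth` (per-gene program classes and
#'   fold-changes), `reference` (the `LayeredReference`), `pathways` and
#'   `config`.
#' @export
simulate_disc <- function(config = disc_sim_config()) {
  set.seed(config$seed)
  ref <- simulate_reference(config)
  genes <- .disc_gene_table(config)
  nb <- is.na(genes$base)
  genes$base[nb] <- rlnorm(sum(nb), meanlog = 0, sdlog = 1)
  W0 <- sum(genes$base)
  size <- 1 / config$dispersion
  batch_cms <- list()
  truth <- list()
  for (bi in seq_len(nrow(config$batches))) {
    blab <- config$batches$label[bi]
    btime <- config$batches$time[bi]
    bfac <- if (config$batch_scale > 0)
      rlnorm(nrow(genes), 0, config$batch_scale) else rep(1, nrow(genes))
    n <- config$n_cells_per_batch
    n_doub <- floor(config$doublet_rate * n)
    n_single <- n - n_doub
    attrs <- .draw_cell_attrs(n_single, config, ref, btime)
    eff <- .effect_matrix(genes, attrs, config, ref)
    lib <- rlnorm(n_single, config$lib_meanlog, config$lib_sdlog)
    mu <- (genes$base * bfac) * eff *
      rep(lib / W0, each = nrow(genes))
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = size),
                  nrow = nrow(genes))
    doub_cnt <- NULL
    if (n_doub > 0) {
      ai <- sample(which(attrs$layer == "AMP"), n_doub, replace = TRUE)
      ei <- sample(which(attrs$layer == "epithelium"), n_doub, replace = TRUE)
      doub_cnt <- cnt[, ai, drop = FALSE] + cnt[, ei, drop = FALSE]
    }
    all_cnt <- cbind(cnt, doub_cnt)
    ids <- sprintf("%s_cell%05d", blab, seq_len(n))
    bt <- rbind(attrs,
                if (n_doub > 0) data.frame(
                  layer = rep(NA_character_, n_doub),
                  position = NA_character_,
                  domain = NA_character_, compartment = NA_character_,
                  sex = NA_character_, phase = NA_character_,
                  amp_type = NA_character_, time = btime,
                  stringsAsFactors = FALSE))
    bt$doublet <- rep(c(FALSE, TRUE), c(n_single, n_doub))
    bt$cell_id <- ids
    bt$batch <- blab
    truth[[blab]] <- bt
    batch_cms[[blab]] <- count_matrix(
      all_cnt, genes$gene, ids,
      data.frame(batch = rep(blab, n), time = rep(btime, n),
                 stringsAsFactors = FALSE))
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- truth$cell_id
  gene_truth <- genes
  gene_truth$fold <- c(landmark = config$marker_fc, sex = 600,
                       direct_tf = config$subtype_fc,
                       indirect_tf = config$subtype_fc,
                       cell_cycle = config$cc_fc, mito = 1,
                       notum_program = config$domain_fc,
                       hinge_program = config$domain_fc,
                       pouch_program = config$domain_fc,
                       pe_program = config$domain_fc,
                       posterior_program = config$compartment_fc,
                       amp_program = config$layer_fc,
                       epi_program = config$layer_fc,
                       direct_program = config$subtype_fc,
                       indirect_program = config$subtype_fc,
                       late_up = config$temporal_fc,
                       late_down = config$temporal_fc,
                       batch_artifact = config$temporal_fc,
                       fgf_ligand = config$pathway_fc,
                       fgf_receptor = config$pathway_fc,
                       hh_receptor = config$pathway_fc,
                       hh_receptor2 = config$layer_fc,
                       uniform_pathway = 1,
                       background = 1)[gene_truth$class]
  list(counts = bind_cells(batch_cms), truth = truth,
       gene_truth = gene_truth, reference = ref,
       pathways = disc_sim_pathways(), config = config)
}

#' Write a simulated bundle as a plain-text fixture directory
#'
#' Emits per-batch Matrix Market triplets under `batches/<label>/`, the
#' spatial reference as `positions.tsv` / `patterns.tsv`, the pathway table
#' as `pathways.csv`, and the truth tables as CSV, all in the formats the
#' analysis modules read back.
#'
#' @param bundle result of [simulate_disc()].
#' @param out_dir output directory (created).
#' @return invisibly, `out_dir`.
#' @export
write_fixture <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  for (blab in unique(bundle$counts$cell_meta$batch)) {
    cm <- subset_cells(bundle$counts, bundle$counts$cell_meta$batch == blab)
    write_counts_mtx(cm, file.path(out_dir, "batches", blab))
  }
  write_reference(bundle$reference,
                  file.path(out_dir, "positions.tsv"),
                  file.path(out_dir, "patterns.tsv"))
  write.csv(bundle$pathways, file.path(out_dir, "pathways.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(bundle$truth, file.path(out_dir, "truth_cells.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(bundle$gene_truth, file.path(out_dir, "truth_genes.csv"),
            row.names = FALSE, quote = FALSE)
  batches <- unique(bundle$counts$cell_meta[, c("batch", "time")])
  write.csv(batches, file.path(out_dir, "batches.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Read a fixture directory back into a simulation-style bundle
#'
#' @param dir a directory written by [write_fixture()].
#' @return list with `counts`, `reference`, `pathways`, `truth` (if present).
#' @export
read_fixture <- function(dir) {
  batches <- read.csv(file.path(dir, "batches.csv"),
                      stringsAsFactors = FALSE)
  cms <- lapply(seq_len(nrow(batches)), function(i) {
    b <- file.path(dir, "batches", batches$batch[i])
    read_counts_mtx(file.path(b, "matrix.mtx"), file.path(b, "features.tsv"),
                    file.path(b, "barcodes.tsv"),
                    batch_label = batches$batch[i],
                    time_label = batches$time[i])
  })
  truth_path <- file.path(dir, "truth_cells.csv")
  list(counts = bind_cells(cms),
       reference = load_reference(file.path(dir, "positions.tsv"),
                                  file.path(dir, "patterns.tsv")),
       pathways = read_pathway_table(file.path(dir, "pathways.csv")),
       truth = if (file.exists(truth_path))
         read.csv(truth_path, stringsAsFactors = FALSE))
}
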