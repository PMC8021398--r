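#' Pipeline configuration
#'
#' Bundles the input location, output directory, seed and every stage's
#' parameters for [run_pipeline()].  Defaults correspond to the reference
#' analysis: per-batch cluster QC at resolution 2.0, 1000 (epithelium) or
#' 2000 (AMP) variable genes per batch, 20 latent dimensions, sex-stratified
#' AMP batches, cell-cycle dimension masking, the three-part DE criterion,
#' and separate AMP/epithelium spatial mapping.
#'
#' @param fixture_dir directory holding the input fixture
#'   (see [write_fixture()] for the layout).
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param seed non-negative integer master seed.
#' @param provider embedding provider id.
#' @param n_latent latent dimensionality.
#' @param resolution clustering resolution.
#' @param qc a [qc_params()] object.
#' @param thr a [de_thresholds()] object.
#' @param tau mapping softmax temperature.
#' @param var_genes_epi,var_genes_amp variable genes per batch for the two
#'   layer subsets.
#' @param layer_markers named list of marker sets for layer annotation.
#' @param domain_markers named list of marker sets for epithelial domain
#'   annotation.
#' @param sex_genes,cc_genes,posterior_genes,anterior_genes,ct_gene,vg_gene
#'   covariate/classifier gene sets.
#' @param sex_stratify refine AMP batch labels to batch x sex before the
#'   final embedding (default `TRUE`).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(fixture_dir, out_dir,
                            seed = 1L,
                            provider = "svd",
                            n_latent = 20,
                            resolution = 2.0,
                            qc = qc_params(),
                            thr = de_thresholds(),
                            tau = 0.1,
                            var_genes_epi = 1000,
                            var_genes_amp = 2000,
                            layer_markers = list(
                              AMP = c("SPARC", "twi"),
                              epithelium = c("Fas3")),
                            domain_markers = list(
                              notum = "pnr", hinge = "zfh2",
                              pouch = "nub", PE = "Ubx"),
                            sex_genes = c("roX1", "roX2"),
                            cc_genes = c(sprintf("cc_%02d", 1:10),
                                         "PCNA", "CycB"),
                            posterior_genes = c("hh", "en"),
                            anterior_genes = "ci",
                            ct_gene = "ct", vg_gene = "vg",
                            sex_stratify = TRUE) {
  if (seed < 0 || seed != round(seed)) stop("seed must be a non-negative integer")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Stage names of the analysis pipeline, in execution order
#' @return character vector of stage ids.
#' @export
pipeline_stages <- function() {
  c("load", "qc", "filter", "harmonize", "covariates", "cluster",
    "annotate", "de", "map", "screen")
}

.need <- function(state, fields, stage) {
  miss <- setdiff(fields, names(state))
  if (length(miss))
    stop("stage '", stage, "' is missing dependencies: ",
         paste(miss, collapse = ", "),
         " (run the earlier stages first)")
}

.stage_load <- function(state, cfg) {
  fx <- read_fixture(cfg$fixture_dir)
  state$counts <- fx$counts
  state$reference <- fx$reference
  state$pathways <- fx$pathways
  state$log <- list(load = list(n_cells = length(fx$counts$cell_ids),
                                n_genes = length(fx$counts$gene_ids)))
  state
}

# per-batch cluster-level QC + layer annotation
.stage_qc <- function(state, cfg) {
  .need(state, "counts", "qc")
  cm <- state$counts
  keep_ids <- character(0)
  layer_of <- character(0)
  flags_all <- list()
  batches <- unique(cm$cell_meta$batch)
  for (bi in seq_along(batches)) {
    b <- batches[bi]
    cmb <- subset_cells(cm, cm$cell_meta$batch == b)
    stats <- compute_cell_stats(cmb)
    nmb <- normalize_total_log(cmb)
    vg <- select_variable_genes(cmb, cfg$var_genes_epi)
    lat <- embed_cells(cmb, vg, embed_params(cfg$n_latent,
                                             provider = cfg$provider,
                                             seed = cfg$seed + bi))
    cl <- snn_cluster(lat, resolution = cfg$resolution,
                      seed = cfg$seed + bi)
    flags <- flag_clusters(stats, nmb, cl, cfg$qc)
    flags$batch <- b
    flags_all[[b]] <- flags
    keep_cl <- flags$cluster[flags$keep]
    marker_genes <- unique(unlist(cfg$layer_markers))
    sc <- scale_genes(subset_norm(nmb, marker_genes))
    ann <- annotate_clusters(sc, cl, cfg$layer_markers)
    cell_layer <- ann$label[match(as.character(cl), ann$cluster)]
    sel <- as.character(cl) %in% keep_cl
    keep_ids <- c(keep_ids, cmb$cell_ids[sel])
    layer_of <- c(layer_of, setNames(cell_layer[sel], cmb$cell_ids[sel]))
  }
  state$qc_flags <- do.call(rbind, flags_all)
  state$layer <- layer_of
  state$counts_qc <- subset_cells(cm, keep_ids)
  state$log$qc <- list(n_retained = length(keep_ids),
                       n_removed = length(cm$cell_ids) - length(keep_ids))
  state
}

# within-subset cell filters (per batch x layer)
.stage_filter <- function(state, cfg) {
  .need(state, c("counts_qc", "layer"), "filter")
  cm <- state$counts_qc
  stats <- compute_cell_stats(cm)
  keep <- character(0)
  reports <- list()
  groups <- split_in_order(cm$cell_ids,
                           paste(cm$cell_meta$batch, state$layer[cm$cell_ids]))
  for (g in names(groups)) {
    res <- filter_cells_within_subset(stats, groups[[g]], cfg$qc)
    keep <- c(keep, res$retained)
    reports[[g]] <- res$report
  }
  state$cell_report <- do.call(rbind, reports)
  state$counts_filtered <- subset_cells(cm, keep)
  state$log$filter <- list(n_retained = length(keep))
  state
}

.stage_harmonize <- function(state, cfg) {
  .need(state, c("counts_filtered", "layer"), "harmonize")
  cm <- state$counts_filtered
  state$nm <- normalize_total_log(cm)
  state$latent <- list()
  state$layer_cells <- list()
  for (ly in c("AMP", "epithelium")) {
    ids <- cm$cell_ids[state$layer[cm$cell_ids] == ly]
    if (length(ids) == 0) next
    sub <- subset_cells(cm, ids)
    nvg <- if (ly == "AMP") cfg$var_genes_amp else cfg$var_genes_epi
    vg <- select_variable_genes(sub, nvg)
    state$latent[[ly]] <- embed_cells(sub, vg,
      embed_params(cfg$n_latent, provider = cfg$provider,
                   seed = cfg$seed + 11L))
    state$layer_cells[[ly]] <- ids
    state$var_genes[[ly]] <- vg
  }
  state$log$harmonize <- lapply(state$layer_cells, length)
  state
}

.stage_covariates <- function(state, cfg) {
  .need(state, c("nm", "latent", "counts_filtered"), "covariates")
  sex <- classify_sex(state$nm, cfg$sex_genes)
  state$sex <- sex$sex
  state$sex_thresholds <- sex$thresholds
  # sex-stratified re-embedding of the AMP subset
  if (isTRUE(cfg$sex_stratify) && !is.null(state$latent$AMP)) {
    ids <- state$layer_cells$AMP
    sub <- subset_cells(state$counts_filtered, ids)
    sub$cell_meta$orig_batch <- sub$cell_meta$batch
    sub$cell_meta$batch <- paste(sub$cell_meta$batch,
                                 state$sex[ids], sep = "_")
    vg <- state$var_genes$AMP
    state$latent$AMP <- embed_cells(sub, vg,
      embed_params(cfg$n_latent, provider = cfg$provider,
                   seed = cfg$seed + 12L))
  }
  # cell-cycle dimension masking, per layer subset
  cc <- intersect(cfg$cc_genes, state$nm$gene_ids)
  if (length(cc) > 0) {
    for (ly in names(state$latent)) {
      ids <- state$layer_cells[[ly]]
      state$latent[[ly]] <- mask_cell_cycle_dimension(
        state$latent[[ly]], subset_norm_cells(
          state$nm, match(ids, state$nm$cell_ids)), cc)
    }
  }
  state$log$covariates <- list(
    n_male = sum(state$sex == "male"), n_female = sum(state$sex == "female"),
    masked_dims = lapply(state$latent, `[[`, "masked_dims"))
  state
}

.stage_cluster <- function(state, cfg) {
  .need(state, c("latent", "nm"), "cluster")
  state$clusters <- list()
  drop_ids <- character(0)
  stats <- compute_cell_stats(state$counts_filtered)
  for (ly in names(state$latent)) {
    ids <- state$layer_cells[[ly]]
    cl <- snn_cluster(state$latent[[ly]], resolution = cfg$resolution,
                      seed = cfg$seed + 21L)
    # second doublet sweep on harmonized clusters
    nm_sub <- subset_norm_cells(state$nm, match(ids, state$nm$cell_ids))
    st_sub <- stats[match(ids, stats$cell_id), , drop = FALSE]
    flags <- flag_clusters(st_sub, nm_sub, cl, cfg$qc)
    bad <- flags$cluster[flags$suspected_doublet]
    drop_ids <- c(drop_ids, ids[as.character(cl) %in% bad])
    state$clusters[[ly]] <- setNames(as.character(cl), ids)
    state$second_sweep <- rbind(state$second_sweep,
                                cbind(flags, layer = ly))
  }
  if (length(drop_ids) > 0) {
    for (ly in names(state$clusters)) {
      keep <- !(names(state$clusters[[ly]]) %in% drop_ids)
      state$clusters[[ly]] <- state$clusters[[ly]][keep]
      state$layer_cells[[ly]] <- setdiff(state$layer_cells[[ly]], drop_ids)
    }
  }
  state$log$cluster <- c(lapply(state$clusters,
                                function(x) length(unique(x))),
                         list(second_sweep_removed = length(drop_ids)))
  state
}

.stage_annotate <- function(state, cfg) {
  .need(state, c("clusters", "nm"), "annotate")
  ann <- list()
  # epithelial domains
  if (!is.null(state$clusters$epithelium)) {
    ids <- names(state$clusters$epithelium)
    nm_sub <- subset_norm_cells(state$nm, match(ids, state$nm$cell_ids))
    genes <- unique(unlist(cfg$domain_markers))
    sc <- scale_genes(subset_norm(nm_sub, genes))
    dom <- annotate_clusters(sc, state$clusters$epithelium, cfg$domain_markers)
    ann$epi_domains <- dom
    state$domain <- setNames(
      dom$label[match(state$clusters$epithelium, dom$cluster)], ids)
  }
  # AMP subtype
  if (!is.null(state$clusters$AMP)) {
    ids <- names(state$clusters$AMP)
    nm_sub <- subset_norm_cells(state$nm, match(ids, state$nm$cell_ids))
    sc <- scale_genes(subset_norm(nm_sub, c(cfg$ct_gene, cfg$vg_gene)))
    amp <- classify_amp_type(sc, state$clusters$AMP, cfg$ct_gene, cfg$vg_gene)
    ann$amp_types <- amp
    state$amp_type <- setNames(
      amp$amp_type[match(state$clusters$AMP, amp$cluster)], ids)
  }
  state$compartment <- classify_compartment(state$nm, cfg$posterior_genes,
                                            cfg$anterior_genes)
  state$annotations <- ann
  state$log$annotate <- list(
    epi_clusters = if (!is.null(ann$epi_domains)) nrow(ann$epi_domains) else 0,
    amp_clusters = if (!is.null(ann$amp_types)) nrow(ann$amp_types) else 0)
  state
}

.stage_de <- function(state, cfg) {
  .need(state, c("clusters", "nm"), "de")
  de <- list()
  if (!is.null(state$clusters$epithelium)) {
    ids <- names(state$clusters$epithelium)
    nm_sub <- subset_norm_cells(state$nm, match(ids, state$nm$cell_ids))
    de$epi_markers <- one_vs_all_markers(nm_sub,
                                         state$clusters$epithelium, cfg$thr)
  }
  if (!is.null(state$clusters$AMP)) {
    ids <- names(state$clusters$AMP)
    de$amp_temporal <- temporal_consistent_de(state$nm, ids, cfg$thr)
  }
  state$de <- de
  state$log$de <- list(
    temporal_genes = if (!is.null(de$amp_temporal))
      nrow(de$amp_temporal$table) else 0)
  state
}

.stage_map <- function(state, cfg) {
  .need(state, c("nm", "reference", "clusters"), "map")
  ids <- c(names(state$clusters$AMP), names(state$clusters$epithelium))
  labels <- c(rep("AMP", length(state$clusters$AMP)),
              rep("epithelium", length(state$clusters$epithelium)))
  nm_sub <- subset_norm_cells(state$nm, match(ids, state$nm$cell_ids))
  state$mapping <- map_layer(nm_sub, state$reference, labels, tau = cfg$tau)
  lm <- rownames(state$reference$patterns)
  state$vish <- vapply(lm, function(g)
    virtual_insitu(state$mapping$weights, nm_sub, g),
    numeric(ncol(state$mapping$weights)))
  state$log$map <- list(n_mapped = length(ids))
  state
}

.stage_screen <- function(state, cfg) {
  .need(state, c("nm", "pathways", "clusters"), "screen")
  ids <- c(names(state$clusters$AMP), names(state$clusters$epithelium))
  nm_sub <- subset_norm_cells(state$nm, match(ids, state$nm$cell_ids))
  annotations <- data.frame(
    layer = ifelse(ids %in% names(state$clusters$AMP), "AMP", "epithelium"),
    domain = state$domain[ids],
    amp_type = state$amp_type[ids],
    stringsAsFactors = FALSE)
  state$screen <- screen_pathways(nm_sub, annotations, state$pathways,
                                  cfg$thr)
  grp <- ifelse(annotations$layer == "AMP",
                paste0("AMP_", annotations$amp_type),
                annotations$domain)
  genes <- intersect(unique(state$pathways$gene), nm_sub$gene_ids)
  sc <- scale_genes(subset_norm(nm_sub, genes))
  state$dotplot <- dotplot_stats(nm_sub, sc, grp, genes)
  group_layers <- setNames(
    ifelse(startsWith(unique(grp), "AMP_"), "AMP", "epithelium"),
    unique(grp))
  state$calls <- complementarity_calls(state$screen, state$dotplot,
                                       as.list(group_layers),
                                       state$pathways, cfg$thr$pct_min)
  state$log$screen <- list(retained = state$screen$retained,
                           n_calls = nrow(state$calls))
  state
}

.stage_fns <- list(load = .stage_load, qc = .stage_qc,
                   filter = .stage_filter, harmonize = .stage_harmonize,
                   covariates = .stage_covariates, cluster = .stage_cluster,
                   annotate = .stage_annotate, de = .stage_de,
                   map = .stage_map, screen = .stage_screen)

#' Run the analysis pipeline
#'
#' Executes the stages in order (per-batch cluster QC, layer split, subset
#' cell filters, harmonization, covariate handling, clustering with a
#' second doublet sweep, annotation, differential expression, spatial
#' mapping, receptor-ligand screen), writes each stage's tables under
#' `config$out_dir`, caches the pipeline state so individual stages can be
#' re-run, and writes a machine-readable manifest (seed, parameters,
#' per-stage counts, output digests).
#'
#' @param config a [pipeline_config()].
#' @param stages stages to execute (default: all, in order).  Running a
#'   later stage without its dependencies cached is an error naming the
#'   missing dependency.
#' @return invisibly, the final pipeline state (a list).
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  all_stages <- pipeline_stages()
  stopifnot(all(stages %in% all_stages))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache <- file.path(config$out_dir, "cache", "state.rds")
  state <- if (identical(stages[1], all_stages[1])) list() else {
    if (!file.exists(cache))
      stop("stage '", stages[1], "' needs cached state from earlier stages; ",
           "none found under ", dirname(cache))
    readRDS(cache)
  }
  for (st in all_stages[all_stages %in% stages]) {
    state <- tryCatch(.stage_fns[[st]](state, config),
                      error = function(e)
                        stop("stage '", st, "' failed: ", conditionMessage(e),
                             call. = FALSE))
  }
  dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
  saveRDS(state, cache)
  .write_outputs(state, config)
  invisible(state)
}

.write_outputs <- function(state, config) {
  out <- config$out_dir
  wcsv <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(out, f), row.names = FALSE, quote = FALSE)
  wcsv(state$qc_flags, "qc_cluster_flags.csv")
  wcsv(state$cell_report, "cell_retention.csv")
  if (!is.null(state$clusters)) {
    cl <- do.call(rbind, lapply(names(state$clusters), function(ly)
      data.frame(cell_id = names(state$clusters[[ly]]), layer = ly,
                 cluster = state$clusters[[ly]],
                 stringsAsFactors = FALSE)))
    rownames(cl) <- NULL
    if (!is.null(state$domain))
      cl$domain <- state$domain[cl$cell_id]
    if (!is.null(state$amp_type) && is.null(cl$amp_type))
      cl$amp_type <- state$amp_type[cl$cell_id]
    if (!is.null(state$sex)) cl$sex <- state$sex[cl$cell_id]
    if (!is.null(state$compartment))
      cl$compartment <- state$compartment[cl$cell_id]
    wcsv(cl, "cell_annotations.csv")
  }
  if (!is.null(state$de$amp_temporal))
    wcsv(state$de$amp_temporal$table, "de_amp_temporal.csv")
  if (!is.null(state$de$epi_markers)) {
    sig <- do.call(rbind, lapply(names(state$de$epi_markers), function(cl) {
      s <- state$de$epi_markers[[cl]]$significant
      if (nrow(s) == 0) return(NULL)
      s$cluster <- cl
      s
    }))
    wcsv(sig, "de_epi_markers.csv")
  }
  if (!is.null(state$vish)) {
    v <- data.frame(position = colnames(state$mapping$weights),
                    state$vish, check.names = FALSE)
    write.table(v, file.path(out, "virtual_insitu.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(state$screen)) wcsv(state$screen$hits, "screen_hits.csv")
  wcsv(state$dotplot, "dotplot_stats.csv")
  wcsv(state$calls, "complementarity_calls.csv")
  # manifest: seed, parameters, per-stage log, digests of the outputs above
  files <- sort_c(setdiff(list.files(out, recursive = FALSE),
                          c("cache", "manifest.json")))
  files <- files[!dir.exists(file.path(out, files))]
  digests <- as.list(tools::md5sum(file.path(out, files)))
  names(digests) <- files
  manifest <- list(
    package = "discatlas",
    version = as.character(utils::packageVersion("discatlas")),
    seed = config$seed,
    parameters = list(provider = config$provider,
                      n_latent = config$n_latent,
                      resolution = config$resolution,
                      tau = config$tau,
                      fdr_max = config$thr$fdr_max,
                      lnfc_min = config$thr$lnfc_min,
                      pct_min = config$thr$pct_min),
    stages = state$log,
    digests = digests)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a synthetic wing-disc fixture directory
#'
#' Thin wrapper over [simulate_disc()] + [write_fixture()].
#'
#' @param out_dir fixture directory to create.
#' @param config a [disc_sim_config()].
#' @return invisibly, the simulation bundle.
#' @export
simulate_fixture <- function(out_dir, config = disc_sim_config()) {
  bundle <- simulate_disc(config)
  write_fixture(bundle, out_dir)
  invisible(bundle)
}
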