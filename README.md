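# discatlas

Single-cell atlas construction and spatial mapping for layered imaginal-disc
tissue — a tested, reusable R implementation of a droplet scRNA-seq analysis
pipeline for the *Drosophila* wing disc and its adult muscle precursors
(AMPs), with a synthetic-data generator that plants full ground truth.

## The problem

The larval wing disc is two tissues in one capture: the columnar disc proper
(DP) and squamous peripodial epithelium (PE) of the disc, and the
mesoderm-derived AMPs adhering to its basal surface.  Analyzing a
multi-batch 10x-style experiment on this system requires a chain of
decisions that are easy to get subtly wrong and hard to validate on real
data, where no ground truth exists:

* **QC and doublets** — clusters of low-complexity cells and AMP–epithelium
  doublet clusters must be removed before anything else.  Doublet clusters
  are recognized by elevated nGene (genes detected per cell) *and*
  co-expression of both layers' markers (*SPARC*/*twi* for AMPs, *Fas3* for
  epithelium).
* **Covariates** — cell sex (the male-specific *roX1*/*roX2* dosage
  compensation RNAs) and cell-cycle phase stratify the data and must be
  removed: sex by classifying cells at the first local minimum of each roX
  gene's expression density and stratifying batches by sex; cell cycle by
  masking the one latent dimension correlated with a cell-cycle score.
* **Markers and temporal change** — marker genes by Wilcoxon rank-sum with a
  three-part criterion (FDR < 0.05, |lnFC| ≥ 0.15, ≥ 15 % of cells
  expressing in one group); time-point contrasts are batch-confounded, so a
  gene counts as temporally regulated only when significant with a
  consistent sign in **every** (early batch, late batch) pairwise
  comparison.
* **Spatial mapping** — cells are mapped onto a binarized three-layer
  reference (AMP, DP, PE) by the Matthews correlation coefficient between
  the cell's binarized landmark-gene vector **b** and each position's
  pattern **p**:

  `MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`

  AMP and epithelial cells are mapped separately.  Scores become
  row-stochastic weights w(c,p) ∝ exp(MCC/τ), and a *virtual in situ* for
  gene g is the weighted average `vISH(g,p) = Σ_c w(c,p)·x(c,g) / Σ_c w(c,p)`.
* **Receptor–ligand screen** — pathways are retained when a ligand or
  receptor is differentially expressed within the epithelium (domain vs
  rest), between direct and indirect AMPs, or between the two layers;
  complementary expression across layers (e.g., an epithelial ligand facing
  an AMP receptor) is then called from percent-expressing statistics.

Every stage is exercised on a negative-binomial simulator
(`simulate_disc()`) that plants layers, proximodistal domains
(notum/hinge/pouch/PE), anterior/posterior compartments, sex, cell-cycle
phase, direct/indirect AMP programs (divergent only at the late time
point), doublets, batch effects, and a matching binarized spatial
reference — so every claim the pipeline makes can be checked against truth.

## Worked example

```r
library(discatlas)

b  <- simulate_disc(disc_sim_config(n_cells_per_batch = 300, seed = 1))
b$counts
#> CountMatrix: 1646 genes x 1200 cells, 4 batches
b$reference
#> LayeredReference: 90 positions (AMP=20, DP=50, PE=20), 23 landmark genes

nm <- normalize_total_log(b$counts)       # ln(1 + count/total * 10,000)
sx <- classify_sex(nm)                    # density-minimum thresholds
table(sx$sex)
#> female   male
#>    693    507
round(sx$thresholds, 3)
#>  roX1  roX2
#> 1.356 1.295

tr  <- b$truth[!b$truth$doublet, ]
mean(sx$sex[tr$cell_id] == tr$sex)        # against planted truth
#> 0.9877

amp <- tr$cell_id[tr$layer == "AMP"]; epi <- tr$cell_id[tr$layer == "epithelium"]
sig <- call_significant(wilcoxon_de(nm, head(amp, 400), head(epi, 400)))
nrow(sig)                                 # three-part criterion
#> 316
head(sig[order(sig$fdr), c("gene", "fdr", "lnfc", "pct_a", "pct_b")], 3)
#>    gene      fdr  lnfc pct_a pct_b
#>   SPARC 3.41e-90  1.87 0.875 0.220
#>     twi 3.41e-90  1.85 0.887 0.260
#>    Fas3 4.91e-83 -1.80 0.220 0.850

nm_epi <- normalize_total_log(subset_cells(b$counts, epi))
res <- map_layer(nm_epi, b$reference, rep("epithelium", length(epi)))
keep <- b$reference$positions$layer != "AMP"
v <- virtual_insitu(res$weights, nm_epi, "nub")[keep]     # wing-pouch marker
cor(v, b$reference$patterns["nub", keep])
#> 0.955
```

The sex classifier recovers 98.8 % of planted labels; the layer contrast
ranks the canonical markers (*SPARC*, *twi*, *Fas3*) first; and the
predicted spatial pattern of the pouch marker *nub* correlates at r = 0.96
with the reference pattern it was never shown.

The full chain — per-batch QC, layer split, subset filters, harmonized
embedding, sex/cell-cycle correction, clustering with a second doublet
sweep, annotation, DE, spatial mapping, and the pathway screen — runs as

```r
simulate_fixture("fixture", disc_sim_config(seed = 7))
state <- run_pipeline(pipeline_config("fixture", "out", seed = 7))
```

writing per-stage CSV/TSV tables and a `manifest.json` (seed, parameters,
per-stage cell counts, output digests) under `out/`.

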