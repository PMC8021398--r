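---
title: "Methods: building and validating a layered wing-disc cell atlas"
author: "discatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a layered wing-disc cell atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(discatlas)
```

This vignette documents the statistical procedures implemented in
`discatlas`, the assumptions behind them, the tunable parameters and their
defaults, what the bundled simulator does and does not emulate, and the
design choices made where the methodology left genuine latitude.

## 1. Data model and normalization

Raw data are sparse genes × cells UMI count matrices (`CountMatrix`), one
per batch, read from 10x-style Matrix Market triplets.  Downstream stages
work on two derived views:

* **Normalized** (`normalize_total_log()`): each cell's counts are divided
  by its total UMIs, multiplied by a scale factor (default 10,000 —
  "counts per ten thousand", the droplet-era convention), and transformed
  as `ln(1 + x)`.  A cell with zero total counts maps to zeros rather than
  NaN.  The `ln(1+x)` form (not `ln x`) keeps zeros at zero and is what
  "natural-log normalized" means throughout.
* **Scaled** (`scale_genes()`): per gene, centered and divided by the
  sample (n − 1) standard deviation across cells, so each non-constant
  gene has mean 0 and SD 1.  Zero-variance genes map to zero.  The sample
  SD is used everywhere an SD appears in the package, for internal
  consistency.  Clipping of scaled values is available (`clip =`) but off
  by default; none of the validation results depend on it.

Mitochondrial genes are recognized by an id prefix (default `"mt:"`, the
FlyBase convention); the prefix is a parameter because annotation styles
differ.

## 2. Cluster-level QC and doublet removal

`flag_clusters()` implements a two-sided cluster heuristic computed from
**cell-level** statistics (mean and sample SD of nGene over all cells, not
over cluster means):

* *low quality*: cluster mean nGene < global mean − 1.0 SD;
* *suspected doublet*: cluster mean nGene > global mean + 1.0 SD **and**
  the cluster co-expresses both layers' marker sets — at least 50 % of its
  cells positive (normalized value > 0) for ≥ 1 AMP marker (*SPARC*,
  *twi*) and the same for the epithelial marker (*Fas3*).

The 50 % co-expression fraction is a package choice (the criterion
"markers for both cell types" names no number); it is exposed in
`qc_params()`.  The doublet signature assumes that a doublet carries
roughly the summed transcriptome of its two parents, hence ~√2–2× the
detected genes; this only discriminates when gene detection is far from
saturated, which is the regime of real droplet data and of the simulator's
defaults.

`filter_cells_within_subset()` applies the within-subset cell filters:
remove cells with nGene strictly outside mean ± 1.5 SD of the subset, and
cells with mitochondrial fraction strictly above mean + 1.5 SD.  Both
statistics are computed **once** on the pristine subset and applied
jointly — the procedure is not iterated, and boundary cells are retained
(strict inequalities).  With approximately normal nGene this removes
~13 % of cells by construction; that is the intended behavior of a
±1.5 SD band, not a defect.

The pipeline applies cluster flags twice — per batch before
harmonization, and again on the harmonized per-layer clusterings — with
identical thresholds both times.

## 3. Variable genes, embedding, clustering

`select_variable_genes()` ranks genes per batch by the variance of
clipped standardized counts: a loess fit (span 0.3, degree 2) of
log10 variance on log10 mean predicts each gene's expected SD, counts are
standardized against it and clipped at √n_cells, and the per-batch top
1000 (epithelial subsets) or 2000 (AMP subsets) are unioned.

`embed_cells()` is a **provider contract**: any function mapping
(counts, gene set, parameters) to a cells × 20 latent matrix can be
registered with `register_embedding_provider()`.  The built-in `"svd"`
provider natural-log normalizes, standardizes each gene *within each
batch* (removing additive and multiplicative per-batch shifts before any
cross-batch comparison), and takes a truncated SVD via the eigendecomposition
of the gene-space crossproduct, with a sign convention (largest-magnitude
loading positive) that makes coordinates fully deterministic.  This is the
package's own deterministic, dependency-light embedding; heavier models
such as a negative-binomial variational autoencoder plug in behind the
same contract, and their training options are passed through untouched.
The built-in provider produces no imputed expression, so spatial mapping
reads normalized values (see §6); an external provider that denoises can
supply imputed values instead.

`snn_cluster()` builds an exact k-nearest-neighbor graph (k = 20,
Euclidean distance on the unmasked latent dimensions, blockwise to bound
memory), weights pairs by the Jaccard overlap of their neighbor sets
pruned below 1/15, and partitions by Louvain modularity at resolution 2.0
(defaults; k and pruning follow common single-cell practice).  Resolution
2.0 deliberately over-clusters; annotation operates on cluster majorities.
The acceptance simulations use ~1,200–5,000 cells; the exact kNN is
quadratic and comfortable to ~20,000 cells.

## 4. Cell sex and cell cycle

`classify_sex()` assumes the male dosage-compensation transcripts
(*roX1*, *roX2*) are near-silent in female cells and high in males, so
each gene's normalized expression is bimodal.  The density is estimated
with `stats::density` (Gaussian kernel, Silverman's rule-of-thumb
bandwidth, 512-point grid) and the threshold is the **leftmost strict
interior local minimum** of the density; a cell is male iff it exceeds the
threshold for either gene.  Two degenerate conventions: a constant gene,
or one whose density is unimodal, contributes no male calls (so all-zero
sex genes yield all-female, the correct call for silent markers).  The
"first local minimum" could also be read as the minimum between the two
dominant modes; the leftmost-minimum reading is used and the thresholds
are returned so users can inspect them.

`mask_cell_cycle_dimension()` summarizes the cell-cycle gene set as the
per-cell mean of scaled expression, correlates every latent dimension with
this score, and masks the single dimension of maximal |Pearson r| iff
|r| ≥ 0.5.  At most one dimension is masked per call; 0.5 operationalizes
"strongly related" (no number exists in the source methodology, whose
diagnostic showed one dominant dimension).  A per-dimension correlation
table is attached to the result.  The summary-score choice (rather than
per-gene correlations) is deliberate; the table reports the evidence
either way.

Sex stratification is removed not by regression but by refining batch
labels to batch × sex for the AMP subset and re-embedding, so the
within-batch standardization absorbs the sex axis.

## 5. Differential expression

`wilcoxon_de()` is a vectorized two-sided Mann–Whitney/Wilcoxon rank-sum
test on normalized values: normal approximation with tie correction and
continuity correction in general, exact tail probabilities
(`stats::pwilcox`) when the pooled sample is ≤ 10 cells with no ties.
The implementation is verified in the test suite against
`stats::wilcox.test` (identical p-values and U statistics) and against
full enumeration of group assignments at small n.

Effect sizes follow the dominant single-cell convention:
`lnFC = ln((mean(expm1 A) + 1) / (mean(expm1 B) + 1))` — the pseudocounted
ratio of de-logged normalized means — plus the fraction of cells with
value > 0 per group.  FDR is Benjamini–Hochberg (`stats::p.adjust`)
applied within each comparison over **all** tested genes; genes are never
pre-filtered before testing, since that would invalidate the FDR.

`call_significant()` applies the three-part rule with its exact boundary
semantics: FDR strictly < 0.05; |lnFC| ≥ 0.15 (inclusive); percent
expressing ≥ 15 % (inclusive) in **either** group.

`temporal_consistent_de()` treats time-point contrasts as batch-confounded
and reports only genes significant in every (early batch, late batch)
pairwise comparison — four pairs in the 2 × 2 design — additionally
requiring a consistent lnFC sign across pairs (the sign requirement can be
disabled).  The reported effect is the natural log of the arithmetic mean
of the per-pair linear fold-change ratios ("ln of the average value"); the
alternative reading, the mean of the per-pair lnFCs, is available via
`average = "log"`.  By Jensen's inequality the default is never smaller.
Time labels are ordered by their leading number, so "96h" precedes "120h"
despite lexicographic order; an explicit `time_order` overrides this.

Rank-sum power at small margins is intrinsically limited: at 30 %
detection and linear fold-change 1.5 with 500 cells per group, roughly
80–85 % of planted genes survive the full three-part criterion in the
most favorable (Poisson, equal-depth) regime, and per-cell depth variation
costs more because normalization breaks count ties and inflates the rank
variance.  The acceptance suite records this measured power; it is a
property of the test at those margins, not an implementation artifact.

## 6. Spatial mapping and virtual in situs

The reference (`LayeredReference`) is a table of positions (id, layer ∈
{AMP, DP, PE}, x, y) plus a binary landmark-gene × position pattern
matrix.  Mapping proceeds per layer group — AMP cells against AMP
positions, epithelial cells against DP ∪ PE (restriction flags exist) —
in three steps:

1. **Binarization** (`binarize_cells()`): for each landmark, the fraction
   f of the layer's positions carrying the pattern sets a threshold at the
   (1 − f) empirical quantile (nearest-rank, "higher" convention) of the
   gene's values over the mapped cells; a cell is positive strictly above
   it.  The cell-population positive fraction then tracks f.  Degenerate
   conventions: f = 1 thresholds at the minimum; a constant gene binarizes
   to all-zero.  Quantile matching assumes cells are roughly uniformly
   drawn from the tissue; strong spatial sampling bias would miscalibrate
   thresholds proportionally.
2. **Scoring** (`mcc_scores()`): the Matthews correlation coefficient of
   the 2 × 2 confusion table between the cell's binary vector and each
   position's pattern.  A zero factor in the denominator yields score 0
   (uninformative) rather than NaN, keeping score matrices finite.
3. **Weights** (`mapping_weights()`): a per-cell softmax over the layer's
   positions, w(c,p) ∝ exp(score/τ) with τ = 0.1.  The transform is
   explicit and configurable because the score-to-weight step of the
   original mapping methodology is not documented; its limits (uniform as
   τ → ∞, argmax as τ → 0) are tested.

`virtual_insitu()` distributes expression over positions as the
weight-weighted average of cell values — a convex combination, so
predictions always lie within the range of observed values; positions with
zero total weight return NA.  With the built-in embedding the expression
source is normalized values; imputed values from an external provider can
be substituted (`map_layer()`'s expression source is the `NormMatrix` it
is handed).

## 7. Receptor–ligand screen

`screen_pathways()` runs three DE contexts — each epithelial domain vs all
other epithelial cells; direct vs indirect AMPs (a single two-sided
comparison, "compared to each other"); all epithelium vs all AMPs — each
over the whole transcriptome with BH within the context, then retains any
pathway with ≥ 1 ligand/receptor gene significant anywhere, recording the
triggering gene and context.  Retention is monotone in the thresholds and
independent of pathway-table row order.

`dotplot_stats()` reports per (group, gene) the fraction of expressing
cells and the mean scaled expression.  `complementarity_calls()` is
presence-based, not significance-based: a retained pathway's ligand
expressed (pct ≥ 15 %) in a group of one layer facing its receptor
expressed in a group of the other layer yields a call.  The 15 % reuses
the DE percent threshold for coherence.  A 19-pathway template CSV
(`inst/extdata/pathways_19_template.csv`) ships with exemplar
ligand/receptor genes per pathway; membership is user-editable, and genes
absent from a dataset are skipped with a warning.

## 8. The synthetic disc: what it emulates, and what it does not

`simulate_disc()` draws counts gene-wise from a negative binomial with
mean = baseline weight × planted fold-changes × per-batch lognormal factor
× per-cell lognormal library size (means are scaled against the fixed
baseline weight total, so planted fold-changes are exact in expectation).
Defaults, chosen once as the simulated study's conditions:

| parameter | default | rationale |
|---|---|---|
| batches | 2 time points × 2 replicates, 1,250 cells each | the two-time-point, replicated design |
| AMP fraction | 0.6 | AMP-dominated captures |
| doublet rate | 0.05 | typical droplet collision rates; exactly ⌊rate·n⌋ per batch, counts summed from one AMP + one epithelial parent |
| NB dispersion | 0.15 | moderate UMI overdispersion |
| library size | lognormal(ln 1500, 0.3) | leaves gene detection unsaturated (~45 %), preserving the doublet nGene signature |
| landmark fold | 10× on a 0.4 baseline | in situ-grade on/off markers (~3 mean counts when on) |
| layer programs | 120 genes × 3× per layer | germ-layer-scale AMP/epithelium divergence |
| domain / compartment folds | 3× (10 genes) / 4× (8 genes + markers) | strong but not caricatured regional programs |
| direct/indirect programs | 40 genes + *ct*/*vg* at 6×, late only | lineage-scale divergence at 120 h; at 96 h the programs are identical unless `divergence_at_96h` |
| sex | *roX1*/*roX2* male-exclusive (600× over a near-zero baseline), 40 % male | male-specific dosage-compensation RNAs |
| cell cycle | 12 genes × 4× in an S-like state, 50 % of cells, in every cluster | the observed two-state stratification |
| batch effect | per-gene lognormal, sd 0.1 | realistic run-to-run wobble; also the source of the single-batch "artifact" genes the temporal filter must reject |

The matching reference is a deterministic grid — 50 DP positions across
notum/hinge/pouch, a 20-position PE outline, 20 AMP positions under the
notum — with layer, domain and compartment markers plus x/y stripe
landmarks that make every position's pattern unique within its layer
(uniqueness is checked; too few stripes is an error).

Not emulated: read-level noise, ambient RNA, UMI collisions, cell-free
droplets, continuous spatial gradients (domains are blockwise), doublet
heterotypic downsampling, and transcriptome-scale gene counts.  Passing
tests therefore demonstrate algorithmic correctness and recoverability
under a faithful-but-idealized generative model; they do not certify
performance on any particular real dataset.

## 9. Pipeline, determinism, problem sizes

`run_pipeline()` chains: per-batch QC clustering → layer split by marker
annotation → per (batch × layer) cell filters → per-layer harmonized
embedding → sex classification and sex-stratified AMP re-embedding →
cell-cycle masking → per-layer clustering with a second doublet sweep →
annotation (domains, AMP subtype, compartments) → DE (epithelial
one-vs-all markers; AMP temporal consistency) → separate-layer spatial
mapping and virtual in situs for all landmarks → pathway screen, dot-plot
statistics and complementarity calls.  Each stage writes CSV/TSV tables;
`manifest.json` records version, seed, parameters, per-stage counts and
md5 digests of every output.  State is cached so individual stages can be
re-run; a missing dependency is reported by name.

Every random step derives its seed from the configuration seed, the
embedding provider is deterministic, and all label orderings are
locale-independent (appearance-order grouping, byte-order sorts), so two
runs with the same inputs and seed are bitwise identical — the property
the determinism check asserts on manifests and digests.

Validation problem sizes — 5,000 cells end-to-end, 1,000 cells × 200
positions for mapping identifiability, 2,000 genes for DE calibration,
2 × 1,250 cells per batch for the temporal filter — were chosen so the
whole suite exercises every stage at realistic scale on a single CPU.

## 10. Known limitations

* The built-in embedding is linear; nonlinear structure (e.g., cycling
  trajectories) is captured only as far as a truncated SVD allows.  The
  provider contract is the intended escape hatch.
* AMP subtype calls compare mean scaled *ct* vs *vg* with a strict
  inequality and no margin; on clusters without planted (or real)
  divergence — e.g., early-time AMPs — the call is noise by construction,
  which is why subtype recovery is evaluated on late-time clusters.
* The doublet heuristic detects doublet **clusters**; isolated doublets
  inside parent clusters are below its resolution, as with the original
  heuristic.
* Quantile binarization assumes the mapped population samples the
  reference roughly uniformly; heavily biased dissociation would shift
  thresholds.
* Rank-sum power at |lnFC| near the 0.15 boundary is modest (§5); users
  hunting subtle temporal shifts should expect the conservative all-pairs
  rule to trade recall for robustness to batch confounding.
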