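Package: discatlas
Title: Single-Cell Atlas Construction and Spatial Mapping for the Drosophila Wing Disc
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a single-cell RNA-seq analysis
    pipeline for layered imaginal-disc tissue: cluster-level quality-control
    and doublet filtering, variable-gene selection and batch-aware latent
    embedding with pluggable providers, shared-nearest-neighbor clustering,
    density-based cell-sex classification and cell-cycle latent-dimension
    masking, Wilcoxon rank-sum differential expression with a three-part
    significance criterion and an all-pairwise temporal-consistency rule,
    Matthews-correlation spatial mapping of cells onto a binarized
    three-layered reference with virtual in situ prediction, and a
    receptor-ligand pathway screen.  Ships a negative-binomial synthetic
    wing-disc generator with fully planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
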