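Package: phosphoRescue
Title: Differential Abundance, Treatment-Rescue Scoring and Network
    Analysis for Label-Free (Phospho)Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of label-free proteomic and
    phosphoproteomic intensity tables from a two-genotype, multi-treatment
    mouse design: replicate quality control, presence/absence calling
    without imputation, per-feature cell-means linear-model contrasts with
    Benjamini-Hochberg adjustment, treatment "rescue" scoring (percentage
    of recovery and its four-class scheme), seed-based protein-protein
    interaction network expansion with exact Poisson edge enrichment,
    degree-distribution fitting and hub detection, phosphosite motif
    composition and consensus matching, novel-object-recognition
    behavioral scoring with PCA, and Spearman screening of molecular
    features against cognition. A synthetic-data generator with known
    ground truth drives testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    pracma,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
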