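Package: brainstem
Title: Two-Tier Reference Mapping of Single-Cell Brain Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical (two-tier) reference mapping for single-cell
    RNA-seq of neural cultures and brain tissue. Query cells are first
    projected onto a whole-brain reference to assign coarse cell type and
    brain-region identity (forebrain, midbrain, hindbrain), with module-score
    confidence filtering; cells assigned to the midbrain are then re-mapped
    onto a high-resolution midbrain reference for fine subtype calls.
    Includes kNN-based quantification of brain-region specificity per cell
    type, gene-module scoring with expression-binned control genes,
    one-vs-rest Wilcoxon marker detection, preranked gene-set enrichment for
    cell-type identity strength, a random-forest ventral/dorsal score, a
    direct-mapping baseline, and a negative-binomial simulator of
    regionalized brain scRNA-seq with ground-truth labels for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    ranger,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
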