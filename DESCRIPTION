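Package: subfam
Title: Structure-Anchored Subfamily Classification of Protein
    Superfamilies and Pangenome Presence/Absence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects protein superfamilies into functional subfamilies by
    combining structure-guided core-region alignment with distance-based
    phylogenetics. Provides exhaustive pairwise protein alignment for
    homolog collection, rigid-body (Kabsch) superposition with iterative
    detection of the structurally conserved core, projection and
    progressive alignment of discontinuous core segments, bootstrapped
    neighbor-joining trees, species-overlap labelling of duplication and
    speciation nodes with hierarchical orthologous-group extraction, and
    catalytic-triad diagnostics. A companion pangenome component converts
    comparative genome hybridization (CGH) score matrices into
    presence/absence calls, filters variable genes, and clusters
    co-occurring genes. Simulators with known ground truth generate every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml
Config/testthat/edition: 3
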