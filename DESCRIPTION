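Package: hindseg
Title: Resolving Hindbrain Segmental Identities from Single-Cell Multiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multimodal (joint RNA +
    chromatin accessibility) single-cell data from the developing zebrafish
    hindbrain. Provides quality-control filtering, depth-normalised log
    transformation, PCA and latent-semantic-indexing embeddings, a bimodal
    shared-nearest-neighbour graph with modularity clustering, one-vs-rest
    marker detection and reference-panel identity assignment, per-cell motif
    accessibility deviation scores, screens for odd/even rhombomere
    periodicity and adjacent-pair co-expression, per-cell mixed-identity
    co-expression statistics, cross-timepoint integration with contribution
    cross-tabulation and residual progenitor-cluster detection, reference
    mapping of query cells, perturbation composition and differential
    expression analysis, and simplified regulatory-network comparison.
    Includes a synthetic multiome generator with planted cluster structure,
    lineages, mixed-identity progenitors and motif enrichments so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    irlba,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
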