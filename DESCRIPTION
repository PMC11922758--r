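Package: hypoatlas
Title: Consensus Cell-Type Trees, Cross-Species Matching, Spatial Region
    Assignment and GWAS Effector Genes for Single-Nucleus Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-level consensus cell-type hierarchies from
    single-nucleus RNA-seq embeddings (Leiden ensembles, hybrid bipartite
    graph consensus, multi-resolution tree reconciliation, marker-based
    pruning with a batch-stratified Wilcoxon rank-sum test), matches
    cluster labels across species by adjusted centroid correlation with
    bipartite graph pruning, assigns transcriptomic clusters to spatial
    regions from deconvolution abundance matrices via MAD-normalized
    scores, and selects GWAS effector genes from bootstrapped cell-type
    specificity and gene association ranks. Ships a synthetic-data
    generator with planted ground truth so the full pipeline is testable
    end to end, plus readers and writers for MTX, TSV, CSV, JSON and
    Newick, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape
Config/testthat/edition: 3
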