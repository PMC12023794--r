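Package: fabgenomics
Title: Comparative Genomics of Fungus-Associated Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for comparative genomics of habitat-classified
    bacterial genome collections, built around the question of what
    distinguishes fungus-associated bacteria from bacteria of other hosts and
    habitats. Provides genome-set curation (quality filtering, per-species
    subsampling, average-nucleotide-identity dereplication), phylogeny-aware
    gene enrichment via phylogenetic generalized least squares with optional
    Pagel's lambda estimation, hypergeometric and odds-ratio habitat
    association scoring of gene orthologs, pathway-completeness profiling with
    chi-squared habitat comparisons, CAZyme consensus filtering and
    substrate-level guild comparisons, and Bray-Curtis ordination with
    PERMANOVA and distance-based redundancy analysis. A synthetic-data
    generator with known ground truth (Yule trees, Brownian-motion gene-count
    effects, planted habitat signals, injected near-clone genomes and designed
    quality-control failures) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    cluster,
    phytools,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
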