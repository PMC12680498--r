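Package: panvine
Title: Pan-Genome Structural Variants and Single-Nucleus Expression
    Integration for Cultivar-Specific Trait Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrative pipeline for nominating candidate genes behind a
    cultivar-specific trait (continuous flowering and bearing in grapevine):
    calls focal-cultivar unique structural variants from a pan-genome
    multi-sample VCF, detects hemizygous genes from long-read deletion calls,
    links genes to unique SVs within a proximity window and tests term
    enrichment, runs a single-nucleus expression stage (quality control,
    log-normalization, variable genes, PCA with a variance-based component
    cutoff, shared-nearest-neighbor clustering, cluster markers, cross-cultivar
    differential expression), and intersects SV-proximal genes with
    differentially expressed genes before TPM normalization and Spearman
    co-expression of the candidates. A synthetic-cohort generator produces
    every input with known truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    jsonlite
Config/testthat/edition: 3
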