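Package: orthani
Title: Pangenome Orthology, ANIb Phenetics and Functional Enrichment for
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of bacterial strain collections:
    best-reciprocal-hit (BRBH) orthology and core/accessory/strain-specific
    pangenome partitioning, Goris-style average nucleotide identity (ANIb)
    with neighbor-joining phenetic clustering, conservation classification of
    reference gene clusters (e.g. metal-resistance operons) across genomes,
    Pfam2GO annotation transfer with hypergeometric over-representation
    testing under Bonferroni correction, and positional (per-contig)
    chi-squared enrichment of differentially expressed genes. Includes a
    Smith-Waterman local aligner (BLOSUM80 protein mode and anchored
    nucleotide mode) so the pipeline runs without external search tools, a
    synthetic pangenome simulator with planted truth for validation, and an
    end-to-end pipeline driver with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    igraph,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
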