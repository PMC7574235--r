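Package: famtrace
Title: Charting Birth-and-Death Evolution of Gene Families by Iterative
    Homology Annotation and Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for studying
    birth-and-death evolution of a multi-copy gene family such as
    perforin-1. Provides six-frame translated homology search
    (seed-and-extend), splice-aware protein-to-genome alignment to build
    exon/intron gene models, pseudogene classification from premature
    stop codons and frameshifts, iterative re-annotation with newly found
    paralogs as queries, synteny-based locus assignment from flanking
    marker genes, protein phylogenetics (center-star alignment,
    neighbor joining, Fitch parsimony, bootstrap support), and
    duplication/loss reconciliation of gene trees against a species tree.
    A synthetic-genome simulator with known ground truth (planted
    multi-exon genes, tandem amplifications, pseudogenes, flanking
    markers, transposon-like repeats, split-contig artifacts) makes every
    stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
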