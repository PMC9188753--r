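Package: ehtmeth
Title: Tile-Based Whole-Genome Bisulfite Methylome Dynamics During the
    Endothelial-to-Haematopoietic Transition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for whole-genome bisulfite sequencing (WGBS)
    methylomes of endothelial cells (EC), hemogenic endothelial cells (HEC)
    and haematopoietic stem and progenitor cells (HSPC) across wild-type
    sibling and dnmt1-mutant zebrafish embryos. Implements consecutive
    500 bp tiling with pooled-count methylation levels, genome-wide
    methylation summaries and per-CpG methylation categories, replicate-level
    Student's t differentially methylated region (DMR) calling with
    Benjamini-Hochberg correction and a shared-CpG recovery rule,
    six-pattern DMR clustering across the three cell types, promoter and
    gene-body annotation with Fisher-exact region-set enrichment, a
    median-of-ratios differential-expression screen, and integration of
    promoter methylation with gene expression through genotype-stratified
    Pearson correlations. A fully seeded synthetic-data generator emulates
    the 3 cell-type x 2 genotype x 3 replicate design with planted DMRs and
    methylation-coupled genes so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
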