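Package: backsplice
Title: Structural Analysis of Circular RNA Isoform Catalogues
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the structural analysis of circular RNA (circRNA)
    isoforms at a multi-exon locus. Parses and canonicalizes catalogues of
    back-spliced exon paths, computes exon-abundance and intron-inclusion
    profiles, detects inverted Alu-class repeat pairs in flanking introns by
    affine-gap global alignment and predicts the back-splice junctions such
    pairs could generate, and tests whether annotated exon-skipping events
    can account for observed circles. A seeded simulator generates loci,
    genomes, repeat tracks and circle catalogues with known ground-truth
    biogenesis labels. Ships a curated catalogue and gene model for the
    ANRIL (CDKN2B-AS1) locus on chromosome 9p21.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
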