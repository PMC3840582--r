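Package: sRNAcascade
Title: Small RNA Annotation Cascade and miRNA Discovery for Plant Leaf
    Libraries
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of plant small RNA sequencing libraries:
    quality filtering and adapter trimming of raw reads, collapsing into
    unique tags with per-library normalized counts, cascading annotation
    against non-coding RNA, repeat and exon references, homology-based
    classification of conserved microRNA families with seed-region
    protection, structural evaluation of novel hairpin precursors folded
    with ViennaRNA, detection of 21-nt phased trans-acting siRNA loci by a
    hypergeometric phasing statistic, complementarity-based microRNA
    target prediction with duplex free-energy filtering, and term-for-term
    Gene Ontology enrichment of predicted target sets.  A synthetic-data
    generator produces libraries with known ground truth so every stage
    can be exercised and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: ViennaRNA (RNAfold and RNAduplex on the PATH)
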