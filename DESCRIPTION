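Package: prokannot
Title: Evidence-Hierarchy Functional Annotation and Structural Curation for
    Prokaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational core of an evidence-driven prokaryotic genome
    annotation workflow. Implements frameshift-tolerant extended translated
    alignment of predicted genes against protein subjects (BER), automated
    structural curation of gene models (start-site selection by evidence
    voting with ribosome-binding-site support, removal of spurious
    overlapping ORFs, detection of interevidence regions), the pFunc
    hierarchical functional-annotation engine combining BER, HMM, LipoP and
    TMHMM evidence, common-name post-processing, locus-tag assignment and
    standard-format output (GFF3, FASTA, TSV). A deterministic synthetic
    fixture generator makes the whole pipeline testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
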