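Package: IgRescue
Title: Resurrecting Dominant Immunoglobulin Chains from Degraded-RNA
    Sequencing Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to recover the dominant antibody expressed in a tissue
    sample from two sequencing libraries of fragmented (e.g. FFPE-derived)
    RNA: a constant-region-primed immunoglobulin amplicon library (Ig-seq)
    and a whole-transcriptome fragment library. The package extracts
    CDR3/junction clonotypes with conserved cysteine and tryptophan/
    phenylalanine anchors, summarises repertoire clonality in a three-layer
    (singleton/doubleton/3+, abundance-quantile, top-5) profile, reconstructs
    full-length heavy- and light-chain variable regions by CDR3-seeded
    3'-to-5' overlap extension of transcriptome reads, and annotates the
    reconstruction against germline V/J alleles (IMGT-style CDR boundaries,
    somatic hypermutation calls, isotype). A synthetic-data generator
    emulating degraded-RNA repertoires with a dominant, heavily mutated IgG
    clone provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, ImmunoOncology, Software
RoxygenNote: 7.3.3
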