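Package: releseq
Title: Simulation and Analysis of Endonuclease-Generated Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bacterial ribosome profiling libraries in which
    footprint 3' ends are generated by the mRNA interferase RelE, which
    cleaves after the second nucleotide of the ribosomal A-site codon.
    Provides a synthetic transcriptome and footprint simulator (stochastic
    translation with cleavage, ribosome rescue and reinitiation; MNase and
    RelE digestion geometry with configurable sequence preferences),
    3'-end density maps and equal-weighted metagene profiles, operon
    position ratio analysis with a rank-sum test, sub-codon reading-frame
    quantification with the NNC-codon shift correction, programmed
    frameshift detection by multinomial change-point segmentation, and
    nuclease sequence-specificity profiling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
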