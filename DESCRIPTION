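Package: pileupCNN
Title: Somatic Variant Refinement from Read Pileups with a Compact
    Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates genuine somatic single-nucleotide variants from
    sequencing artefacts by encoding the read pileup around each candidate
    locus as a numeric tensor (one-hot base identity, base and mapping
    quality, read direction) for the tumour track, the matched germline
    track, and additional context tracks that share a library preparation,
    and classifying the depth-concatenated tensor with a compact
    convolutional neural network. Includes the full evaluation machinery
    (stratified cross-validation, repeated random splits, geometric
    subsampling studies, binomial subgroup tests with Bonferroni
    correction), a confusion-matrix reconciliation solver for printed
    metric tables, and a seeded simulator of labelled pileups covering
    strand-bias, misalignment, noise, and library-preparation artefact
    classes, so the whole pipeline is testable end to end without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    Rsamtools,
    GenomicRanges,
    IRanges,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
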