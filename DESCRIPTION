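Package: xenostroma
Title: Stroma Transcriptome Dissection for Two-Species Xenograft
    Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the host (stroma) transcriptome from
    mixed two-species hybridization data, as arises when human cancer
    cells are xenografted into mouse bone. Implements cross-species
    probe masking (k-mer seed-and-extend identification of
    cross-hybridizing oligonucleotide probes and probe-set
    redefinition), quantile normalization and species-specific
    probe-set summarization, empirical-Bayes moderated t-statistics
    with local false discovery rate estimation, sequential
    signature-subtraction curation of a core stroma response
    signature, hypergeometric signature-overlap tests, and promoter
    motif enrichment against resampled gene backgrounds. A synthetic
    two-species data generator with known ground truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    limma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
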