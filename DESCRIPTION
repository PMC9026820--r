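Package: insuscan
Title: Insulator Loop Anchor Prediction, Boundary Refinement and Variant
    Scoring from DNA Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts CTCF/cohesin-mediated insulator loop anchors from
    2000 bp DNA windows with a reverse-complement-symmetric (Siamese)
    convolutional neural network, refines fuzzy anchor annotations to
    ~40 bp via one-dimensional gradient-weighted class activation mapping,
    and quantifies non-coding variant impact as the wild-type minus mutant
    anchor-probability delta. Includes a JASPAR motif scanner with exact
    score-distribution p-values, a dataset builder that types negatives
    from ChIP-seq/ChIA-PET/ATAC-seq peak logic, training and evaluation
    harnesses (leave-one-chromosome-out, cross-cell-line), and a synthetic
    planted-motif benchmark generator so the whole pipeline is testable
    without external downloads.
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
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
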