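Package: conjseq
Title: Quantifying Conjugative Plasmid Transfer and Transfer-Gene Essentiality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for studies of conjugative plasmid transfer
    in vitro and in the mammalian gut. Implements high-density transposon
    mutagenesis (Tn-seq) insertion-site calling from alignments, depth
    normalisation, per-gene read counting with end trimming, depletion-ratio
    statistics and core-set-calibrated gene essentiality calls; colony-count
    (CFU) back-calculation from serial-dilution spot assays, conjugation
    frequencies per recipient with limit-of-detection censoring, fold changes
    and log-scale correlation and ANOVA summaries; pairwise global alignment
    with percent identity and core/soft-core/accessory pan-genome
    classification of plasmid gene families; and a synthetic-data generator
    producing annotated plasmids, insertion libraries, sequencing reads,
    dilution assays and plasmid families with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
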