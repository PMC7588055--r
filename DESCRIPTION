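Package: repliRAT
Title: Replication Timing Profiles and Regions of Altered Timing from
    Fraction-Resolved Repli-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares DNA replication-timing programs between two cell-cycle
    conditions (for example the mitotic cycle and the endocycle) from
    window-level Repli-seq counts of early, mid and late S-phase fractions.
    Implements the Repliscan-style normalization chain (fixed-window binning,
    hypergeometric downsampling, 2C-reference blacklist detection, 1x genome
    coverage scaling, reference-ratio normalization, Haar wavelet smoothing),
    a caller for compensated Regions of Altered Timing (RATs) with
    per-chromosome difference thresholds and two-stage gap merging,
    centromere-focused timing summaries, genomic permutation enrichment tests,
    window copy-number screening between ploidy levels, ChIP
    enrichment-per-DNA-content statistics with a histone redeposition model,
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
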