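Package: vcbench
Title: Benchmarking, Combination and Contamination Analysis of Variant Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating small-variant callsets (SNVs, insertions,
    deletions) against a high-confidence truth set. Variant representations are
    regularized by shared-base trimming and left-alignment of indels so that
    equivalent calls in repetitive sequence compare identically; callsets are
    matched on (type, start, end) keys within confident regions to produce
    false-positive and false-negative rates. Multiple callsets can be combined
    by union, intersection, detection-frequency binning, three-way Venn counts
    and genotype-quality ROC sweeps. A site-level contamination simulator with
    a diploid genotype-likelihood caller quantifies detection power as a
    mixture of sample and reference-homozygous contaminant reads at constant
    coverage, and clinical annotation tables can be overlapped with callsets to
    report which tool combinations miss clinically significant variants. A
    synthetic-data generator (repeat-rich references, truth sets,
    tool-emulating callsets, region files, clinical tables) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
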