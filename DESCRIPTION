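Package: peakbench
Title: Benchmarking Epigenomic Peak and Fragment Sets Against Reference Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking epigenomic profiling experiments (for
    example CUT&Tag) against a reference peak set (for example ENCODE
    ChIP-seq): capture precision, recall and F1 over genomic intervals,
    fragment-level quality metrics (FRiP, cross-mark specificity,
    duplication rate, fragment-length QC, fingerprint curves, binned
    coverage correlation with quantile normalization), stratified
    comparison of captured versus missed reference peaks, chromatin-state
    and promoter annotation, and a synthetic-data generator with known
    ground truth that makes the whole suite testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
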