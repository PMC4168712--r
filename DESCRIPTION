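Package: tagalign
Title: Seed-and-Extend Short-Read Alignment with Tag-Based Candidate Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A gapped short-read aligner built on a bidirectional FM-index
    over the reference genome concatenated with its reverse complement.
    Reads are anchored by greedy extraction of maximal, minimally
    overlapping seeds; every exact seed match grants a score to the fixed
    length genome partition ('tag') estimated to contain the read start,
    accumulated in a reset-free open-addressing hash table that tracks the
    top-scoring tags. Each candidate tag is then aligned precisely with a
    gap-filling banded dynamic program in differential-position (offset)
    coordinates, producing SAM output with CIGAR strings and edit
    distances, for single-end and paired-end reads. Includes a
    dwgsim-style Illumina read simulator with per-read ground truth and a
    recall/precision evaluator for mapping benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    knitr
SystemRequirements: C++17
Config/testthat/edition: 3
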