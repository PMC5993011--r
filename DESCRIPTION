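Package: bacsvm
Title: Bacterial Promoter Window Extraction and SVM Grid-Search Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds labeled promoter / non-promoter datasets from bacterial
    genomes and exhaustively grid-searches support-vector-machine
    formulations, kernels and cost/gamma values to find the best promoter
    classifier. Extracts fixed-length (default 80 nt) promoter windows from
    a genome given an annotation table of absolute positions and binding
    sequences, falling back to exact sequence search when a position misses;
    ships the Bacillus subtilis sigma-factor catalog with its sigma-54 /
    sigma-70 domain grouping; encodes sequences as one-hot or k-mer
    frequency features; samples overlap-free or dinucleotide-shuffled
    negatives; evaluates every grid cell by seeded stratified k-fold
    cross-validation and reports accuracy, specificity and sensitivity. A
    synthetic-genome generator with planted -35/-10 promoter motifs makes
    the whole pipeline testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    kernlab,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
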