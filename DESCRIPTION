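Package: rollscreen
Title: Rolling Silent-Baseline Scoring for Deep Mutational Scanning Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores pooled saturation-mutagenesis (deep mutational scanning)
    proliferation screens against a rolling silent-mutation baseline: per-variant
    log2 fold-changes are converted to z-scores using the mean and standard
    deviation of silent-variant fold-changes in a local codon window, aggregated
    across replicates, and thresholded into loss-of-function calls and
    residue-level intolerance profiles. Includes a synthetic screen generator
    with known ground truth for validation by parameter recovery, concordance
    analysis against variant-effect predictors (CADD, REVEL, AlphaMissense),
    interval algebra for spike-in normalized chromatin profiling workflows
    (reproducible peaks, union-merge, gained/lost/persistent partitions,
    accessibility-expression quadrant concordance), post-trajectory molecular
    dynamics statistics (contact frequencies, interaction-energy
    difference-in-differences with dual significance thresholds), and
    label-free proteomics filtering, down-shifted imputation and differential
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
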