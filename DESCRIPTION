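Package: kaskit
Title: Analysis Toolkit for KAS-seq and spKAS-seq Single-Stranded DNA Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, peak integration, and downstream analysis of
    kethoxal-assisted single-stranded DNA sequencing (KAS-seq) and its
    strand-specific variant (spKAS-seq). Computes transcription-cycle
    metrics (pausing, elongation, and termination indices) per gene,
    classifies single-stranded transcribing (SST) enhancers against their
    flanking shores, detects R-loops from strand-imbalanced read coverage
    with a negative-binomial window test and RNase H sensitivity
    filtering, and classifies time-course signal trajectories as steadily
    or transiently regulated with nested constant/sigmoid/impulse model
    fits. Includes seeded synthetic-data generators so the full pipeline
    is testable without external datasets, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
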