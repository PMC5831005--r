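Package: docseq
Title: Differential Open Chromatin Site Analysis for ATAC-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies differential open chromatin sites (DOCS) between two
    sample groups from ATAC-seq peak-by-sample count tables using a
    negative-binomial Wald test with compound significance thresholds, and
    characterizes them by permutation-based region-set enrichment (log2 fold
    enrichment and a directional log2FE-ratio statistic), regulatory-domain
    binomial and hypergeometric pathway tests, Fisher overlap tests, and
    sample-label permutation validation. Includes a fully seeded synthetic
    data generator with planted ground truth (peak atlases, negative-binomial
    counts, chromatin-state segmentations, gene models, term sets, and
    coupled expression counts) and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    MASS,
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
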