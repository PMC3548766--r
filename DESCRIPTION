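Package: batchalloc
Title: Optimal Sample-to-Batch Allocation for Genomics Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Allocates collected samples to the batches of a genomics
    experiment (plates, or the chips within plates) so that biological
    groups of interest and categorical confounders are distributed as
    evenly as possible across batches. Implements block randomization of
    the optimization strata formed by crossing the covariates, followed
    by either a greedy swap-based shuffle optimizer or pool selection
    over many block-randomized setups, minimizing the least-squares
    deviation between realized and expected batch-by-stratum counts.
    Includes Pearson chi-square diagnostics of batch association, a
    synthetic study generator for unbalanced sample collections, plate
    layout models with well exclusions, and CSV sample-sheet output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
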