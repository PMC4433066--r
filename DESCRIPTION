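Package: splicediverge
Title: Comparative Alternative-Splicing Analysis Between Species Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies alternative-splicing (AS) events (intron retention,
    exon skipping, alternative donor/acceptor sites and their composites)
    from transcript models in GTF, characterizes splice-junction
    dinucleotides against a genome, calls orthologs by reciprocal best
    hits from tabular alignment output, compares per-gene AS levels
    between two species groups with an expression-matched four-fold /
    presence-absence rule, relates AS to gene-architecture features and
    transposable-element content of retained introns, summarizes variant
    tables, and models detection saturation with sequencing depth by
    binomial read thinning. Ships a synthetic-data generator that plants
    every one of these signals with a ground-truth record, so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
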