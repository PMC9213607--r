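Package: telex
Title: Locus-Level Transposable-Element Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for locus-resolved transposable-element (TE)
    expression analysis from assembled transcripts: identity/coverage
    filtering and unique-locus assignment of transcript alignments, TPM/CPM
    quantification, TMM cross-sample normalization, paired and unpaired
    negative-binomial likelihood-ratio differential expression, TE
    class/family enrichment, 15-state chromatin annotation with mixed-state
    collapsing, cis gene assignment, and an entropy/Boruta/random-forest
    classifier with subject-aware data splits. Includes a synthetic-data
    generator that emulates a paired pre/post phenoconversion cohort with an
    independent control group, so every stage is testable against planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    MASS,
    cluster,
    ranger,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
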