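Package: cdsgen
Title: Age-Conditioned Generation and Evaluation of Child-Directed Speech Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling child-directed speech (CDS) as a function of
    child age: transcript ingestion and normalization, 3-month age binning,
    WordPiece subword tokenization, an age-conditioned decoder-only
    transformer language model with a training loop, stochastic top-k
    corpus generation, and a full evaluation battery covering lexical
    richness (type-token ratios by part of speech), Jensen-Shannon lexical
    divergence, dependency-based syntactic complexity, perplexity profiling,
    novelty analysis, subsampled effect sizes, and acoustic-prosodic
    measures (pitch height and variability, tempo, vowel duration) from
    forced alignments and pitch tracks. Ships a synthetic age-stratified
    CDS corpus generator with gold Universal Dependencies annotation so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    withr,
    jsonlite,
    ggplot2,
    signal,
    stats,
    utils,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
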