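Package: reghmm
Title: Regression Hidden Markov Models for Segmenting Genes by
    Histone-Mark/Expression Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a mixture of linear regressions with Markov-dependent
    hidden states and distance-dependent transition probabilities
    (a regression hidden Markov model) to segment genes into regulatory
    states by the strength of the relationship between promoter-proximal
    histone-modification signal and gene expression. Provides Baum-Welch
    estimation with multi-start, Viterbi decoding, BIC state-number
    selection, a no-Markov mixture-of-regressions baseline, preprocessing
    from signal tracks (strand-aware TSS window averaging, rank-based
    inverse-normal standardization, gene filtering), downstream state
    characterization (per-state regressions, signed per-variable R-squared,
    enrichment and resampling tests), held-out prediction via per-state
    multivariate-normal profiles, and a fully specified synthetic-data
    generator for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
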