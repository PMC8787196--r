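Package: groomsyntax
Title: Syntax, Stereotypy and Variability Analysis of Drosophila Grooming Ethograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying variation and variability in fly grooming
    behavior from frame-resolution ethograms over a seven-action alphabet
    (five grooming actions, walking, standing). Provides ethogram input/output
    and short-bout denoising, run-length bout encoding, behavioral feature
    extraction (action proportions, temporal progression vectors, first-order
    transition-probability syntax, bout-duration histograms), stereotypy
    metrics (Markov entropy rate and Levenshtein edit distance between
    anterior grooming motifs), pairwise group comparisons with Holm
    multiple-comparison correction, cross-validated multinomial-logistic
    classification with permutation chance levels, low-dimensional embedding,
    and a semi-Markov ethogram simulator with motif-structured syntax,
    anterior-to-posterior progression, and optogenetic stimulation windows
    for fully synthetic, reproducible pipeline runs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    nnet,
    car,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
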