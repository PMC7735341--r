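Package: songculture
Title: Quantitative Comparison of Humpback Whale Song Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for matching symbolically transcribed humpback whale songs
    across populations and years. Implements the Levenshtein similarity index
    (LSI) on unit and theme sequences, median-string summarisation of string
    sets, agglomerative clustering of similarity matrices with linkage
    selection by cophenetic correlation and multiscale-bootstrap
    approximately-unbiased (AU) edge support, Dice's similarity index on theme
    presence/absence, random-forest validation of qualitative unit
    classifications, and daily song-presence summarisation for duty-cycled
    passive acoustic recordings. Includes a generative model of multi-lineage
    song cultures (theme evolution, cultural revolution, transcription noise)
    so every stage of the pipeline can be exercised end to end on synthetic
    corpora with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
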