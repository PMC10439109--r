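Package: blinkr
Title: Ultrafast All-Pairs Cosine Similarity Scoring of Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores cosine similarity and matching-ion counts between all pairs
    of tandem mass spectra (MS/MS) by the blur-and-link approach: fragment m/z
    values are discretized into integer bins, linked across a mass tolerance by
    a uniform blur kernel, and scored for all spectrum pairs at once with a
    single sparse matrix product. Includes MGF reading and writing, the standard
    noise-filtering and square-root intensity preprocessing, analog (neutral
    loss) search by precursor or fixed mass shift, a precise greedy
    alignment-based cosine used to re-score top hits, and a synthetic spectrum
    generator with controllable fragment overlap for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
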