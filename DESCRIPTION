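Package: lexcompnet
Title: Gated Recurrent Network Model of Spoken-Word Recognition and
    Visual-World Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a gated recurrent unit (GRU) network that maps
    dynamically unfolding phonological representations of spoken words onto
    static aggregated semantic, visual, and lexical representations, together
    with a simulator of target-absent visual-world trials. Provides dynamic
    phonological encodings with co-articulation interpolation, preprocessing
    of semantic and visual embedding matrices (outlier replacement, principal
    component reduction, median binarization), Jaccard-similarity recognition
    scoring, full-batch Nesterov-momentum training with hand-derived
    backpropagation through time, learning-progress diagnostics split by word
    length and cohort size, and a synthetic vocabulary generator so that the
    whole pipeline runs without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
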