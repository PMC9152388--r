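Package: cner
Title: Character-Level Clinical Named Entity Recognition with Dilated
    Convolutions, Multi-Head Attention and a Linear-Chain CRF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A character-level sequence-labeling toolkit for clinical named
    entity recognition in electronic medical records. Characters are embedded
    as the sum of token, segment and (sinusoidal or learned) position vectors,
    encoded by an iterated dilated convolutional network with shared
    parameters, re-weighted by multi-head scaled dot-product self-attention,
    and decoded by a linear-chain conditional random field trained by exact
    maximum likelihood with Viterbi decoding. Includes BIO span tagging over
    six clinical entity types, CoNLL and span-annotated corpus readers with
    period-based sentence splitting, strict entity-level evaluation, several
    adaptive-gradient optimizers with a Lookahead wrapper, and a deterministic
    generator of synthetic EMR-like labeled corpora so the whole pipeline is
    testable without access to restricted clinical data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
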