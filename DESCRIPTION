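Package: picosminer
Title: Hybrid Neural and Rule-Based PICOS Evidence Extraction from Chinese RCT Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the ten PICOS evidence elements (population size, age,
    source, diagnostic criteria, therapy, adverse events, shedding, missing
    data, blinding, randomization) from Chinese randomized-controlled-trial
    text. A character-level BiLSTM-CRF sequence labeler locates coarse
    evidence spans, an ordered regular-expression rule set refines them to
    fine-grained values (match/judge/split actions with fallback
    pass-through), and an evaluation suite scores extraction with strict and
    relaxed span matching, entity-level precision/recall/F1, and Cohen's
    kappa for annotation quality control. A seeded synthetic-corpus generator
    emulates annotated RCT paragraphs so every stage is trainable and
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
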