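Package: chemner
Title: Chemical Named Entity Recognition with Conditional Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemical named entity recogniser for scientific text. Combines
    chemistry-aware sentence splitting and tokenisation, a chemical
    knowledge-rich feature set (dictionary longest-match tags, chemical
    affixes, element symbols, basic name segment counts, word shapes),
    a linear-chain conditional random field sequence labeller with per-token
    marginal confidences, and two rule-based recall-boosting post-processing
    heuristics (parenthesised abbreviation recognition and chemical
    composition-based token relabelling). Includes CHEMDNER-style corpus
    readers and writers, mention-level (CEM) and document-indexing (CDI)
    evaluation with micro and macro averaging, and a seed-reproducible
    synthetic corpus generator so the full pipeline can be trained and
    evaluated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
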