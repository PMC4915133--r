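Package: edgppi
Title: Protein-Protein Interaction Passage Detection with Extended Dependency Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based extraction of protein-protein interaction (PPI) mentions
    and evidence passages from full-text biomedical articles. Sentence parses and
    gene/protein named-entity annotations are combined into an extended dependency
    graph (EDG): entity mentions are merged into single vertices, PropBank-style
    numbered argument edges (arg0/arg1) are added around lexical trigger words to
    unify active, passive and nominalized realizations, extra-syntactic relations
    (part-whole, is-a, member-collection, coreference) are detected, and argument
    edges are propagated along them to a fixpoint. A small set of trigger-anchored
    predicate-argument rules is then matched against the EDG with a backtracking
    labeled-subgraph matcher to extract interacting protein pairs. Document-level
    pairs seed passage detection: sentences with direct hits are extended by
    experimental-technique and trigger co-occurrence rules, merged into passages
    of consecutive sentences, and flagged when they likely report newly validated
    interactions. Input and output use the BioC XML interchange format; dependency
    parses are ingested from CoNLL-U or Stanford-dependencies text, or from a
    pluggable parser adapter. Includes a hand-built fixture corpus of canonical
    PPI sentence constructs, a templated synthetic sentence generator, and a
    precision/recall/F evaluator for pairs, sentences and passages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
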