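# edgppi

Rule-based extraction of protein–protein interaction (PPI) mentions and
evidence passages from dependency-parsed biomedical text, built around
**extended dependency graphs** (EDGs).

## What it does

Biomedical articles assert the same interaction in many surface forms —
*A binds B*, *B is bound by A*, *the binding of A to B*, *A-binding protein
B* — and scatter the evidence across Results, figure captions and
Discussion. `edgppi` implements a deterministic, lexicon-driven pipeline
that neutralizes this variation:

1. **EDG construction** (`build_edg`): a sentence's dependency parse is
   normalized to collapsed dependencies, protein mentions are merged into
   single vertices, nine construction rules add PropBank-style `arg0`/`arg1`
   edges around lexical triggers (unifying active, passive, nominalized,
   adjectival, relative-clause and gerundive realizations), extra-syntactic
   relations (part-whole, is-a, member-collection, coreference) are
   detected, and argument edges are propagated along them to a fixpoint.
2. **Pair extraction** (`extract_pairs`): four small predicate–argument
   patterns (direct verb, relational noun, and two indirect two-trigger
   shapes) are matched against the EDG with a backtracking subgraph
   matcher.
3. **Passage detection** (`detect_passages`): sentences with direct hits
   seed two gated extension rules (experimental-technique keywords;
   trigger + known-pair co-occurrence); annotated sentences are merged into
   passages of consecutive sentences and flagged when they likely report a
   newly validated interaction.
4. **I/O and evaluation**: BioC XML collections in and out, CoNLL-U /
   Stanford-dependencies parse readers plus a parser-adapter contract, and
   a P/R/F scorer for pairs, sentences and confusion counts.

The package also ships a hand-built gold-parse fixture corpus covering
thirteen canonical PPI constructs plus multi-sentence passage cases, and a
templated synthetic sentence generator used for end-to-end property tests.

## Worked example

```r
library(edgppi)
lex <- default_lexicon()

case <- load_fixture("table1_row01")
case$sentence
#> [1] "HFE binds to the transferrin receptor"

edg <- build_edg(case$graph, case$mentions, lex)
cat(edg_to_lines(edg), sep = "\n")
#> arg0(binds-2, HFE-1) [R1]
#> arg1(binds-2, transferrin receptor-6) [R1]

extract_pairs(edg, lex)[, c("name_a", "name_b", "trigger", "rule_id")]
#>   name_a               name_b trigger rule_id
#> 1    HFE transferrin receptor    bind      1a
```

Document-level passage detection on the shipped two-sentence
Results/Discussion fixture — the Discussion sentence is picked up by the
trigger co-occurrence extension, gated on the pair extracted in Results:

```r
kt <- load_fixture("kap_tap")
for (p in detect_passages(kt$doc, kt$parses, lex))
  cat(sprintf("sentences %s | %-21s | new_ppi=%s | pairs: %s\n",
              paste(p$sentence_indices, collapse = ","), p$evidence, p$new_ppi,
              paste(p$pairs$name_a, "--", p$pairs$name_b, collapse = "; ")))
#> sentences 1 | direct                | new_ppi=TRUE | pairs: Kap beta2B -- TAP
#> sentences 2 | trigger_cooccurrence  | new_ppi=FALSE | pairs: Kap beta2B -- TAP
```

Scoring from confusion counts (percentages, half-up rounding to one
decimal):

```r
unlist(score_counts(236, 84, 30))
#> precision    recall   f_value
#>      73.8      88.7      80.5
```

A command-line driver for whole BioC collections is installed at
`system.file("scripts", "detect_ppi_passages.R", package = "edgppi")`.

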