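---
title: "Extended dependency graphs for PPI extraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended dependency graphs for PPI extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgppi)
lex <- default_lexicon()
```

This vignette documents the method implemented by **edgppi**: rule-based
extraction of protein–protein interaction (PPI) pairs from dependency-parsed
sentences, and detection of the passages in a full-text article that report
them. The pipeline is deterministic and lexicon-driven; there is no trained
model.

## 1. From parse to extended dependency graph

The unit of analysis is one sentence with (a) a dependency parse and (b)
gene/protein mention annotations, both of which arrive from upstream tools
(the package ships file readers for CoNLL-U and a line-based
Stanford-dependencies text format, plus a parser-adapter contract for live
parsers). Construction of the *extended dependency graph* (EDG) proceeds in
four stages, all visible below on a Table-1-style fixture sentence.

```{r}
case <- load_fixture("table1_row01")
case$sentence
edg <- build_edg(case$graph, case$mentions, lex)
cat(edg_to_lines(edg), sep = "\n")
```

**Stage 1 — normalization.** Uncollapsed parses are normalized into the
collapsed-dependencies convention the rules are written against:
`prep` + `pobj` chains become single `prep_<word>` edges (`prepc_<word>` for
clausal complements, `agent` for passive *by*), and `conj` + `cc` pairs become
`conj_<word>`. `normalize_deps()` is idempotent, which the test suite checks
as a property.

**Stage 2 — entity merging.** Each annotated mention is merged into a single
vertex headed by its rightmost token inside the span; edges incident to
non-head mention tokens are re-attached to the head. This makes a
multi-token name such as *transferrin receptor* one graph vertex, so rules
never have to reason about name-internal structure.

**Stage 3 — numbered arguments.** Trigger words (see §3) receive
PropBank-style `arg0` (agent-like) and `arg1` (patient-like) edges through
nine construction rules, the point of which is voice and category
neutralization: active, passive, nominalized, adjectival, relative-clause and
gerundive realizations of the same proposition end in the same
`arg0`/`arg1` configuration.

| rule | construction | sketch |
|------|-------------|--------|
| R1 | active verb | `nsubj` → arg0; `dobj`/`prep_to`/`prep_with` → arg1 |
| R2 | passive verb (VBN) | `nsubjpass` → arg1; `agent`/`prep_by`/`prep_to`/`prep_with` → arg0 |
| R3 | *between X and Y* | `prep_between` + `conj_and` → arg0 + arg1 |
| R4 | nominalization | `prep_of` → arg0; `prep_to`/`prep_with` → arg1; with `prep_by` present the mapping flips to the passive-nominal reading (`prep_by` → arg0, `prep_of` → arg1) |
| R5 | adjectival participle | modified noun → arg0; incorporated noun → arg1 (both required) |
| R6 | reduced relative (`vmod`) | modified noun → arg1; `prep_to` → arg0 |
| R7 | relative pronoun | *which/that* substituted by the antecedent before R1/R2 apply |
| R8 | null-argument gerund | gerund under `prep_by`/`prepc_by` inherits the governing verb's subject as arg0 |
| R9 | relational noun (*complex*, *dimer*) | `nn`/`prep_of`(+`conj_and`) dependents → two arg0 edges |

```{r}
# one pair set for three surface realizations of the same proposition
for (id in c("fig1_active", "fig1_passive", "fig1_nominal")) {
  p <- extract_pairs(build_edg(load_fixture(id)$graph,
                               load_fixture(id)$mentions, lex), lex)
  cat(id, ":", paste(p$name_a, "--", p$name_b), "\n")
}
```

**Stage 4 — extra-syntactic relations and propagation.**
`detect_extra_relations()` adds four semantic edge types: `part_whole`
(*the BIR3 domain of XIAP*, driven by a part-noun list), `member_collection`
(*proteins such as …*, driven by a collection-noun list), `is_a` (copular
and appositive definitions, with abbreviation appositions validated by a
right-to-left character-matching test, cf. `is_valid_abbreviation()`), and
`coref` (parenthesized aliases). `propagate_args()` then copies every
argument edge along these relations to a fixpoint: whole → part,
collection → member, general → specific, both ways across `coref`, and
head → conjunct across `conj_*` edges. Propagated edges carry a
`propagated:<relation>` provenance tag. Propagation never creates a
self-argument on the trigger, so it cannot route *through* the trigger
vertex — the test oracle exploits exactly this by computing reachability
with the trigger deleted.

Including `conj_*` in the propagation relation is a deliberate design
choice: coordination distribution is handled once, uniformly, in the
propagation stage rather than separately inside each of R1–R9, and a
combined-construct fixture checks that coordination- and
apposition-derived `arg1` edges appear in the expected numbers:

```{r}
f3 <- load_fixture("fig3")
e3 <- build_edg(f3$graph, f3$mentions, lex)
a1 <- e3$arg_edges[e3$arg_edges$label == "arg1", ]
table(a1$provenance)
```

## 2. Predicate–argument rules and the matcher

Pair extraction matches four small graph patterns (`ppi_rule_patterns()`)
against the finished EDG:

* **1a** — an interaction/PTM verb with `arg0` and `arg1` protein arguments;
* **1b** — a relational noun trigger with two `arg0` protein arguments;
* **2a/2b** — two-trigger patterns for indirect assertions (*A blocks the
  activation of B by C*): an indirect-trigger verb whose argument is itself a
  process trigger carrying the protein arguments.

`match_pattern()` is a backtracking labeled-subgraph matcher: pattern
vertices are assigned injectively to EDG vertices that satisfy the slot's
vertex predicate (entity / trigger-class / POS), and pattern edges are
checked against the EDG edge set. Patterns mentioning only `arg0`/`arg1`
are matched against the argument edges alone. Worst-case cost is
exponential in pattern size, but patterns have at most four vertices and
sentences tens of vertices, so matching is effectively instantaneous; the
matcher is verified against a brute-force enumeration oracle on hundreds of
random graphs. Extracted pairs are post-processed: coreference/is-a groups
are collapsed to one representative mention, self-pairs and same-name pairs
are suppressed, and duplicate mention pairs keep their first supporting
rule.

```{r}
case <- load_fixture("table1_row03")
case$sentence
extract_pairs(build_edg(case$graph, case$mentions, lex), lex)[
  , c("name_a", "name_b", "trigger", "rule_id")]
```

## 3. Lexicon

All rules are anchored on a trigger lexicon (`trigger_lexicon()`):
interaction verbs, PTM verbs, relational noun triggers, indirect-assertion
verbs, process nouns (generated `-ion` nominalizations plus *activity*),
exactly five experimental-technique keywords (*2-hybrid, BIFC,
cosedimentation, ITC, pulldown*), part/collection noun lists, and
sentence-initial goal phrases. The shipped default covers every trigger
used in the documentation and fixtures; production use would load a fuller
list via `load_lexicon()` (YAML/JSON). `trigger_base()` maps nominalized
and gerundive surface lemmas back to their verb lemma (*binding → bind*,
*interaction → interact*), preferring derived bases over the surface form
itself.

## 4. Passage detection

At the document level (BioC XML in, BioC XML out; offsets are 0-based
half-open, sentence indices 1-based document-wide):

1. **Direct**: every sentence whose parse yields a pair under §2.
2. **Technique extension**: sentences containing a technique keyword *and*
   at least two mentions forming an already-extracted pair.
3. **Trigger co-occurrence extension**: sentences containing a trigger
   (in any surface form) and two mentions forming an already-extracted pair,
   e.g. a Discussion sentence restating a Results finding.
4. Annotated sentences are merged into **passages** — maximal runs of
   consecutive sentences within one section — each carrying its strongest
   evidence level (`direct` > `technique` > `trigger_cooccurrence`).
5. Each passage gets a **new-PPI flag**: set when the passage sits in a
   Results section, in the Abstract of a document without full text, in a
   Results-context subsection title or figure caption, or in a sentence
   opening with an experimental goal phrase.

Both extension rules are *gated* on a direct pair, so passage detection can
add sentences but never new pairs — an invariance the acceptance suite
checks. The two-sentence worked example:

```{r}
kt <- load_fixture("kap_tap")
ps <- detect_passages(kt$doc, kt$parses, lex)
for (p in ps)
  cat(sprintf("sentences %s | %-21s | new_ppi=%s\n",
              paste(p$sentence_indices, collapse = ","),
              p$evidence, p$new_ppi))
```

## 5. Evaluation arithmetic

`score_counts()` implements the standard percentage P/R/F with 0/0 defined
as 0 and half-up rounding to one decimal, `score_pairs()` matches
order-free normalized name pairs per document (with an optional alias map),
and `score_sentences()` compares (document, sentence-index) sets. Two rows
of the published reference tables are internally inconsistent with their
own confusion counts (a precision printed as 77.2 where 557/722 gives 77.1,
and a recall printed as 64.6 where 370/567 gives 65.3); the package asserts
the formula-true values and records the discrepancy in its tests.

## 6. Fixtures and the synthetic generator

The shipped fixture corpus (`fixture_ids()`, `load_fixture()`) contains
hand-built gold parses for thirteen canonical PPI constructs, three voice
variants of one proposition, two propagation showcases, and a two-sentence
Results/Discussion document. Fixtures are defined once in code and exported
to `inst/extdata` (Stanford-deps text + YAML sidecar + a BioC collection); a
test keeps the shipped files in sync. Tokenization in the fixtures is
parser-style: punctuation is split, and complex names such as `(HVEM)-L`
follow the bracketing the rules expect.

`generate_fixture()` complements the hand-built cases with templated
synthetic ones: 13 construct templates × any interaction verb × sampled
protein names, with the expected pair set derived from template semantics
— giving hundreds of end-to-end recovery cases per test run.

```{r}
g <- generate_fixture("coordination", "associate", c("TRAF2", "RAD51", "MDM2"))
g$sentence
```

## 7. Limitations

* The shipped lexicon is a documented minimal default, not the full
  deployment trigger list; recall on real corpora depends directly on
  lexicon coverage.
* No parser or NER is bundled; quality is bounded by the upstream parse and
  mention annotations supplied through the adapters.
* Extra-syntactic relation detection is pattern-based (part/collection noun
  lists, appositions, parenthesized aliases) and does not attempt general
  coreference resolution.
* Corpus-level replication of published table rows requires the external
  corpora those rows were computed on; the package reproduces the scorer
  arithmetic and all sentence-level constructions, which is what the test
  suite certifies.
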