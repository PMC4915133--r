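#!/usr/bin/env Rscript
# Regenerates the shipped fixture data files under inst/extdata from the
# in-code fixture definitions (R/fixtures.R). Run from the package root after
# changing the fixture corpus:
#   Rscript tools/build_fixtures.R
# A test (test-fixtures.R) asserts the shipped files stay in sync.

pkgload::load_all(".", quiet = TRUE)

dir.create("inst/extdata/fixtures", recursive = TRUE, showWarnings = FALSE)

ids <- setdiff(fixture_ids(), "kap_tap")
cases <- lapply(ids, load_fixture)

# 1. all sentence parses, stanford-deps text format
write_stanford_deps(lapply(cases, `[[`, "graph"),
                    "inst/extdata/fixtures/cases.deps")

# 2. sidecar: mentions, expected pairs, construct tags, document composition
sidecar <- list(
  cases = lapply(cases, function(case) list(
    case_id = case$case_id,
    sentence = case$sentence,
    mentions = lapply(seq_len(nrow(case$mentions)), function(i)
      as.list(case$mentions[i, ])),
    expected_pairs = lapply(case$expected_pairs, as.list),
    construct_tags = as.list(case$construct_tags))),
  documents = list(list(
    case_id = "kap_tap",
    sections = list(list(name = "results", sentences = list("kap_tap_s1")),
                    list(name = "discussion", sentences = list("kap_tap_s2"))),
    expected_pairs = list(list("Kap beta2B", "TAP")))))
yaml::write_yaml(sidecar, "inst/extdata/fixtures/cases.yaml")

# 3. example BioC collection: the kap_tap document plus the 13 construct rows
kt <- load_fixture("kap_tap")
row_ids <- sprintf("table1_row%02d", 1:13)
row_docs <- lapply(row_ids, function(id) {
  case <- load_fixture(id)
  bioc_document_from_parts(id, list(list(
    name = "results", type_raw = "results",
    sentences = case$sentence, mentions = list(case$mentions))))
})
write_collection(c(list(kt$doc), row_docs), NULL,
                 "inst/extdata/example_collection.xml")

# 4. lexicon config equivalent to default_lexicon(), for load_lexicon()
lex <- default_lexicon()
yaml::write_yaml(unclass(lex)[c("ppi_verbs", "ptm_verbs", "noun_triggers",
                                "indirect_triggers", "process_triggers",
                                "technique_keywords", "part_nouns",
                                "collection_nouns", "goal_phrases")],
                 "inst/extdata/lexicon.yaml")

cat("wrote", length(ids), "sentence cases + kap_tap document\n")
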