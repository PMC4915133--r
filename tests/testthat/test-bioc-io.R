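example_xml <- system.file("extdata", "example_collection.xml",
                           package = "edgppi")

write_minimal_bioc <- function(lines) {
  path <- tempfile(fileext = ".xml")
  writeLines(c("<?xml version='1.0' encoding='UTF-8'?>",
               "<collection><source>t</source><date>d</date><key>k</key>",
               lines, "</collection>"), path)
  path
}

test_that("minimal one-sentence zero-annotation collection reads", {
  path <- write_minimal_bioc(c(
    "<document><id>d1</id><passage>",
    "<infon key='type'>abstract</infon><offset>0</offset>",
    "<sentence><offset>0</offset><text>Nothing here.</text></sentence>",
    "</passage></document>"))
  docs <- read_collection(path)
  expect_length(docs, 1)
  d <- docs[[1]]
  expect_equal(d$doc_id, "d1")
  expect_length(d$sections, 1)
  expect_equal(d$sections[[1]]$name, "abstract")
  expect_equal(nrow(document_sentences(d)), 1L)
  expect_equal(nrow(d$mentions), 0L)
})

test_that("fixture collection resolves mentions to sentences", {
  docs <- read_collection(example_xml)
  ids <- vapply(docs, `[[`, "", "doc_id")
  d <- docs[[which(ids == "table1_row01")]]
  expect_equal(nrow(d$mentions), 2L)
  expect_setequal(d$mentions$text, c("HFE", "transferrin receptor"))
  expect_equal(d$mentions$sentence_index, c(1L, 1L))
  # spans check out against the document text
  s <- document_sentences(d)
  m <- d$mentions[d$mentions$text == "HFE", ]
  expect_equal(substr(s$text[1], m$start + 1L, m$end), "HFE")
})

test_that("mention crossing a sentence boundary is dropped with a warning", {
  path <- write_minimal_bioc(c(
    "<document><id>d1</id><passage>",
    "<infon key='type'>results</infon><offset>0</offset>",
    "<sentence><offset>0</offset><text>AB binds.</text>",
    "<annotation id='a1'><infon key='type'>protein</infon>",
    "<location offset='7' length='6'/><text>s. Som</text></annotation>",
    "</sentence>",
    "<sentence><offset>10</offset><text>Something else.</text></sentence>",
    "</passage></document>"))
  expect_warning(docs <- read_collection(path), "crosses sentence boundaries")
  expect_equal(nrow(docs[[1]]$mentions), 0L)
})

test_that("annotation offsets outside the document text are an error", {
  path <- write_minimal_bioc(c(
    "<document><id>d1</id><passage>",
    "<infon key='type'>results</infon><offset>0</offset>",
    "<sentence><offset>0</offset><text>Short.</text>",
    "<annotation id='a9'><infon key='type'>protein</infon>",
    "<location offset='100' length='3'/><text>xyz</text></annotation>",
    "</sentence></passage></document>"))
  expect_error(read_collection(path), "a9")
})

test_that("mention text mismatching the document substring is an error", {
  path <- write_minimal_bioc(c(
    "<document><id>d1</id><passage>",
    "<infon key='type'>results</infon><offset>0</offset>",
    "<sentence><offset>0</offset><text>HFE binds.</text>",
    "<annotation id='a1'><infon key='type'>protein</infon>",
    "<location offset='0' length='3'/><text>XXX</text></annotation>",
    "</sentence></passage></document>"))
  expect_error(read_collection(path), "does not match")
})

test_that("overlapping sentence spans are a validation error", {
  path <- write_minimal_bioc(c(
    "<document><id>d1</id><passage>",
    "<infon key='type'>results</infon><offset>0</offset>",
    "<sentence><offset>0</offset><text>One two three.</text></sentence>",
    "<sentence><offset>5</offset><text>two three four.</text></sentence>",
    "</passage></document>"))
  expect_error(read_collection(path), "overlapping")
})

test_that("unmapped section types fall back to other; mapping is table-driven",
{
  expect_equal(edgppi:::map_section("RESULTS", default_section_map()),
               "results")
  expect_equal(edgppi:::map_section("weird_thing", default_section_map()),
               "other")
  custom <- c(default_section_map(), weird_thing = "methods")
  expect_equal(edgppi:::map_section("weird_thing", custom), "methods")
  # non-gene/protein annotation types are filtered by the allow-list
  path <- write_minimal_bioc(c(
    "<document><id>d1</id><passage>",
    "<infon key='type'>results</infon><offset>0</offset>",
    "<sentence><offset>0</offset><text>HFE binds.</text>",
    "<annotation id='a1'><infon key='type'>disease</infon>",
    "<location offset='0' length='3'/><text>HFE</text></annotation>",
    "</sentence></passage></document>"))
  docs <- read_collection(path)
  expect_equal(nrow(docs[[1]]$mentions), 0L)
  docs2 <- read_collection(path, entity_types = "disease")
  expect_equal(nrow(docs2[[1]]$mentions), 1L)
})

test_that("read -> write -> read round-trips documents structurally", {
  docs <- read_collection(example_xml)
  path <- tempfile(fileext = ".xml")
  write_collection(docs, NULL, path)
  back <- read_collection(path)
  expect_length(back, length(docs))
  for (i in seq_along(docs)) {
    a <- docs[[i]]; b <- back[[i]]
    expect_equal(b$doc_id, a$doc_id)
    expect_equal(document_sentences(b), document_sentences(a))
    expect_equal(b$mentions[order(b$mentions$start), ],
                 a$mentions[order(a$mentions$start), ],
                 ignore_attr = TRUE)
    expect_equal(vapply(b$sections, `[[`, "", "name"),
                 vapply(a$sections, `[[`, "", "name"))
  }
})

test_that("passage annotations are emitted with offsets, infons and pairs", {
  kt <- load_fixture("kap_tap")
  anns <- detect_passages(kt$doc, kt$parses, default_lexicon())
  path <- tempfile(fileext = ".xml")
  write_collection(list(kt$doc), list(anns), path)
  xml <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(
    xml, "//annotation[infon[@key='type']='PPI_passage']")
  expect_length(nodes, 2)
  ev <- vapply(nodes, function(n)
    xml2::xml_text(xml2::xml_find_first(n, "./infon[@key='evidence']")), "")
  expect_setequal(ev, c("direct", "trigger_cooccurrence"))
  # the direct annotation covers exactly sentence 1's span
  dnode <- nodes[[which(ev == "direct")]]
  loc <- xml2::xml_find_first(dnode, "./location")
  s1 <- document_sentences(kt$doc)[1, ]
  expect_equal(as.integer(xml2::xml_attr(loc, "offset")), s1$offset)
  expect_equal(as.integer(xml2::xml_attr(loc, "length")), nchar(s1$text))
  pairs_infon <- xml2::xml_text(
    xml2::xml_find_first(dnode, "./infon[@key='pairs']"))
  expect_match(pairs_infon, "^m[0-9]+\\|m[0-9]+\\|associate\\|1a$")
  newppi <- vapply(nodes, function(n)
    xml2::xml_text(xml2::xml_find_first(n, "./infon[@key='new_ppi']")), "")
  expect_setequal(newppi, c("true", "false"))
})

test_that("dangling sentence index fails before any file is written", {
  kt <- load_fixture("kap_tap")
  bad <- passage_annotation(99L, "technique")
  path <- tempfile(fileext = ".xml")
  expect_error(write_collection(list(kt$doc), list(list(bad)), path),
               "unknown sentence index 99")
  expect_false(file.exists(path))
})

test_that("sentence-local coordinate conversion is the identity", {
  docs <- read_collection(example_xml)
  for (d in docs) {
    sents <- document_sentences(d)
    for (idx in sents$index) {
      local <- sentence_mentions(d, idx)
      if (nrow(local) == 0L) next
      off <- sents$offset[sents$index == idx]
      orig <- d$mentions[d$mentions$sentence_index == idx, , drop = FALSE]
      expect_equal(local$start + off, orig$start)
      expect_equal(local$end + off, orig$end)
      # and the sentence substring equals the mention text
      stext <- sents$text[sents$index == idx]
      expect_equal(substr(rep(stext, nrow(local)), local$start + 1L,
                          local$end), local$text)
    }
  }
})
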