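lex <- default_lexicon()

# A small document builder: sentences with given section names and mention
# name lists; returns doc plus a parses list of NULL (text-only sentences).
text_doc <- function(doc_id, rows) {
  # rows: list of list(section, text, mentions = character vector)
  secs <- list()
  for (r in rows) {
    men <- if (length(r$mentions %||% character(0)) > 0L) {
      starts <- integer(0); ends <- integer(0)
      pos <- 0L
      for (nm in r$mentions) {
        at <- regexpr(nm, substring(r$text, pos + 1L), fixed = TRUE)
        stopifnot(at > 0L)
        starts <- c(starts, pos + as.integer(at) - 1L)
        ends <- c(ends, pos + as.integer(at) - 1L + nchar(nm))
        pos <- ends[length(ends)]
      }
      data.frame(mention_id = NA_character_, text = r$mentions,
                 start = starts, end = ends, entity_type = "protein")
    } else NULL
    secs[[length(secs) + 1L]] <- list(
      name = r$section, sentences = r$text,
      mentions = if (is.null(men)) NULL else list(men))
  }
  # merge consecutive rows with the same section name into one section
  merged <- list()
  for (s in secs) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$name == s$name) {
      last$sentences <- c(last$sentences, s$sentences)
      last$mentions <- c(last$mentions %||% list(NULL),
                         s$mentions %||% list(NULL))
      merged[[length(merged)]] <- last
    } else {
      s$mentions <- s$mentions %||% list(NULL)
      merged[[length(merged) + 1L]] <- s
    }
  }
  bioc_document_from_parts(doc_id, merged)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

kap_pairs <- function() {
  kt <- load_fixture("kap_tap")
  extract_document(kt$doc, kt$parses, lex)
}

test_that("passage_annotation enforces consecutiveness and direct evidence", {
  expect_error(passage_annotation(c(1L, 3L), "direct"), "diff")
  expect_error(passage_annotation(1L, "direct"), "non-empty pair")
  expect_error(passage_annotation(1L, "bogus"))
  a <- passage_annotation(2:4, "technique")
  expect_s3_class(a, "passage_annotation")
})

test_that("known_pair_index groups support rows by normalized pair", {
  pairs <- kap_pairs()
  known <- known_pair_index(pairs)
  expect_length(unclass(known), 1L)
  e <- unclass(known)[[1]]
  expect_setequal(c(e$norm_a, e$norm_b), c("kapbeta2b", "tap"))
  expect_equal(nrow(e$support), 1L)
})

test_that("name matching tolerates surface decoration both ways", {
  expect_true(edgppi:::name_matches("flagtaggedstrap", "strap"))
  expect_true(edgppi:::name_matches("strap", "flagtaggedstrap"))
  expect_false(edgppi:::name_matches("strap", "grb2"))
  expect_false(edgppi:::name_matches("", "strap"))
})

test_that("technique extension fires only for known pairs with a keyword", {
  doc <- text_doc("t1", list(
    list(section = "results", text = "A binds B strongly.",
         mentions = c("A", "B")),
    list(section = "results",
         text = "A 2-hybrid assay confirmed A with B.",
         mentions = c("A", "B")),
    list(section = "results", text = "A 2-hybrid assay of A with C.",
         mentions = c("A", "C")),
    list(section = "results", text = "A and B were used.",
         mentions = c("A", "B"))))
  known <- known_pair_index(data.frame(
    doc_id = "t1", sentence_index = 1L, mention_a = "m1", mention_b = "m2",
    name_a = "A", name_b = "B", trigger = "bind", rule_id = "1a"))
  anns <- extend_by_technique(doc, known, lex)
  expect_length(anns, 1L)
  expect_equal(anns[[1]]$sentence_indices, 2L)   # not 3 (unknown pair),
  expect_equal(anns[[1]]$evidence, "technique")  # not 4 (no keyword)
})

test_that("technique keywords match hyphen/space variants", {
  doc <- text_doc("t1", list(
    list(section = "results", text = "Pull down of A with B.",
         mentions = c("A", "B"))))
  known <- known_pair_index(data.frame(
    doc_id = "t1", sentence_index = 9L, mention_a = "m1", mention_b = "m2",
    name_a = "A", name_b = "B", trigger = "bind", rule_id = "1a"))
  anns <- extend_by_technique(doc, known, lex)
  expect_length(anns, 1L)
})

test_that("trigger co-occurrence extension needs trigger + known pair, and
           skips sentences where the rules already extracted that pair", {
  kt <- load_fixture("kap_tap")
  pairs <- kap_pairs()
  known <- known_pair_index(pairs)
  anns <- extend_by_trigger(kt$doc, known, lex, edgs = kt$parses)
  idx <- vapply(anns, function(a) a$sentence_indices[1], 1L)
  expect_true(2L %in% idx)    # "the direct interaction of TAP with ..."
  expect_false(1L %in% idx)   # sentence 1 already has the direct extraction
})

test_that("assemble_passages merges adjacent runs within one section only", {
  doc <- text_doc("t1", list(
    list(section = "results", text = "S one."),
    list(section = "results", text = "S two."),
    list(section = "results", text = "S three."),
    list(section = "discussion", text = "S four.")))
  pr <- data.frame(doc_id = "t1", sentence_index = 1L, mention_a = "m1",
                   mention_b = "m2", name_a = "A", name_b = "B",
                   trigger = "bind", rule_id = "1a")
  anns <- list(passage_annotation(1L, "direct", pr),
               passage_annotation(2L, "technique"),
               passage_annotation(4L, "technique"))
  merged <- assemble_passages(anns, doc)
  expect_length(merged, 2L)
  expect_equal(merged[[1]]$sentence_indices, 1:2)
  expect_equal(merged[[1]]$evidence, "direct")   # strongest label retained
  expect_equal(merged[[2]]$sentence_indices, 4L) # section boundary blocks 3|4
})

test_that("new-PPI criteria: results section, abstract fallback, results
           captions, goal phrases", {
  pr <- data.frame(doc_id = "t1", sentence_index = 1L, mention_a = "m1",
                   mention_b = "m2", name_a = "A", name_b = "B",
                   trigger = "bind", rule_id = "1a")
  # results section present: results passage flagged, discussion not
  d1 <- text_doc("t1", list(
    list(section = "abstract", text = "A binds B."),
    list(section = "results", text = "A binds B here."),
    list(section = "discussion", text = "A binds B elsewhere.")))
  f1 <- flag_new_ppi(list(passage_annotation(1L, "direct", pr),
                          passage_annotation(2L, "direct", pr),
                          passage_annotation(3L, "direct", pr)), d1, lex)
  expect_equal(vapply(f1, `[[`, TRUE, "new_ppi"), c(FALSE, TRUE, FALSE))

  # no results section: abstract passages are flagged
  d2 <- text_doc("t2", list(
    list(section = "abstract", text = "A binds B."),
    list(section = "discussion", text = "More text.")))
  f2 <- flag_new_ppi(list(passage_annotation(1L, "direct", pr)), d2, lex)
  expect_true(f2[[1]]$new_ppi)

  # fig captions and subsection titles inherit the surrounding major section
  d3 <- text_doc("t3", list(
    list(section = "results", text = "Main result text."),
    list(section = "fig-caption", text = "A binds B (Figure 2)."),
    list(section = "discussion", text = "Discussion text."),
    list(section = "fig-caption", text = "Another caption.")))
  f3 <- flag_new_ppi(list(passage_annotation(2L, "direct", pr),
                          passage_annotation(4L, "direct", pr)), d3, lex)
  expect_true(f3[[1]]$new_ppi)   # caption in results context
  expect_false(f3[[2]]$new_ppi)  # caption in discussion context

  # goal-phrase sentences are flagged wherever they are
  d4 <- text_doc("t4", list(
    list(section = "discussion",
         text = "To investigate whether A binds B, we did X.")))
  f4 <- flag_new_ppi(list(passage_annotation(1L, "direct", pr)), d4, lex)
  expect_true(f4[[1]]$new_ppi)
  d5 <- text_doc("t5", list(
    list(section = "discussion", text = "We failed to investigate A.")))
  f5 <- flag_new_ppi(list(passage_annotation(1L, "direct", pr)), d5, lex)
  expect_false(f5[[1]]$new_ppi)  # phrase must start the sentence

  # flagging is idempotent
  f4b <- flag_new_ppi(f4, d4, lex)
  expect_equal(vapply(f4b, `[[`, TRUE, "new_ppi"),
               vapply(f4, `[[`, TRUE, "new_ppi"))
})

test_that("detect_passages yields the documented kap_tap annotations", {
  kt <- load_fixture("kap_tap")
  ps <- detect_passages(kt$doc, kt$parses, lex)
  expect_length(ps, 2L)
  expect_equal(ps[[1]]$sentence_indices, 1L)
  expect_equal(ps[[1]]$evidence, "direct")
  expect_true(ps[[1]]$new_ppi)
  expect_equal(ps[[2]]$sentence_indices, 2L)
  expect_equal(ps[[2]]$evidence, "trigger_cooccurrence")
  expect_false(ps[[2]]$new_ppi)
})

test_that("passage extension never changes the extracted pair set (property)",
{
  kt <- load_fixture("kap_tap")
  before <- pair_set(extract_document(kt$doc, kt$parses, lex))
  ps <- detect_passages(kt$doc, kt$parses, lex)
  after <- pair_set(do.call(rbind, lapply(ps, `[[`, "pairs")))
  expect_identical(after, before)
})

test_that("write_passages_tsv summarises passages", {
  kt <- load_fixture("kap_tap")
  ps <- detect_passages(kt$doc, kt$parses, lex)
  path <- tempfile(fileext = ".tsv")
  write_passages_tsv(ps, kt$doc, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$evidence, c("direct", "trigger_cooccurrence"))
})
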