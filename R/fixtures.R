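# ---------------------------------------------------------------------------
# Fixture corpus: hand-built CCProcessed-style parses, mentions and expected
# pairs for the canonical PPI sentence constructs (active, passive,
# nominalization, adjective, relative clauses, coordination, null argument,
# is-a, apposition, member-collection, part-whole, combination), the three
# voice/nominalization variants of "activate", and a two-sentence
# Results/Discussion document exercising the trigger co-occurrence passage
# rule. Hand-built parses keep the test suite deterministic and free of any
# parser model download.
#
# Token mini-DSL: whitespace-separated specs "text|POS[|lemma]"; a leading
# "~" glues the token to the previous one (no space in the sentence text).
# Edge mini-DSL: whitespace-separated "label(gov,dep)" with token indices.

fx_parse_tokens <- function(spec) {
  parts <- strsplit(trimws(spec), "[[:space:]]+")[[1]]
  glue <- startsWith(parts, "~")
  parts <- sub("^~", "", parts)
  fields <- strsplit(parts, "|", fixed = TRUE)
  text <- vapply(fields, `[[`, "", 1)
  pos <- vapply(fields, `[[`, "", 2)
  lemma <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else tolower(f[[1]]), "")
  n <- length(text)
  start <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && !glue[i]) cur <- cur + 1L
    start[i] <- cur
    cur <- cur + nchar(text[i])
  }
  data.frame(index = seq_len(n), text = text, lemma = tolower(lemma),
             pos = pos, start = start, end = start + nchar(text))
}

fx_sentence_text <- function(tokens) {
  txt <- strrep(" ", max(tokens$end))
  for (i in seq_len(nrow(tokens))) {
    substr(txt, tokens$start[i] + 1L, tokens$end[i]) <- tokens$text[i]
  }
  txt
}

fx_parse_edges <- function(spec) {
  if (!nzchar(trimws(spec))) return(empty_edge_df())
  parts <- strsplit(trimws(spec), "[[:space:]]+")[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z0-9_:$]+)\\(([0-9]+),([0-9]+)\\)$", parts))
  bad <- parts[vapply(m, length, 1L) == 0L]
  if (length(bad) > 0L) stop("bad edge spec: ", bad[[1]])
  data.frame(label = vapply(m, `[[`, "", 2),
             gov = vapply(m, function(x) as.integer(x[[3]]), 1L),
             dep = vapply(m, function(x) as.integer(x[[4]]), 1L))
}

# mention spec: list(tokens = c(from, to)) or list(text = "...", occ = 1)
fx_mentions <- function(specs, tokens, text) {
  out <- empty_mention_df()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (!is.null(sp$tokens)) {
      start <- tokens$start[tokens$index == sp$tokens[1]]
      end <- tokens$end[tokens$index == sp$tokens[length(sp$tokens)]]
      mtext <- substr(text, start + 1L, end)
    } else {
      hits <- gregexpr(sp$text, text, fixed = TRUE)[[1]]
      occ <- sp$occ %||% 1L
      if (hits[1] < 0L || length(hits) < occ)
        stop("mention text '", sp$text, "' not found in sentence")
      start <- as.integer(hits[occ]) - 1L
      end <- start + nchar(sp$text)
      mtext <- sp$text
    }
    out <- rbind_df(out, data.frame(
      mention_id = sp$id %||% paste0("m", i), text = mtext,
      start = start, end = end,
      entity_type = sp$type %||% "protein"))
  }
  out
}

fx_case <- function(case_id, tokens, edges, mentions, expected, tags) {
  tok <- fx_parse_tokens(tokens)
  text <- fx_sentence_text(tok)
  men <- fx_mentions(mentions, tok, text)
  graph <- depgraph(tok, fx_parse_edges(edges),
                    normalized = TRUE, sent_id = case_id, text = text)
  list(case_id = case_id, sentence = text, graph = graph, mentions = men,
       expected_pairs = expected, construct_tags = tags)
}

tk <- function(...) list(tokens = c(...))

fixture_case_specs <- function() {
  list(
    fx_case("table1_row01",
      "HFE|NNP binds|VBZ|bind to|TO the|DT transferrin|NN receptor|NN",
      "nsubj(2,1) prep_to(2,6) det(6,4) nn(6,5)",
      list(tk(1, 1), tk(5, 6)),
      list(c("HFE", "transferrin receptor")), c("active")),

    fx_case("table1_row02",
      paste("Plasminogen|NNP activator|NN inhibitor|NN 1|CD (|-LRB- ~PAI|NNP",
            "~)|-RRB- is|VBZ|be bound|VBN|bind to|TO vitronectin|NN in|IN",
            "plasma|NN ~.|."),
      paste("nn(3,1) nn(3,2) num(3,4) appos(3,6) punct(6,5) punct(6,7)",
            "nsubjpass(9,3) auxpass(9,8) prep_to(9,11) prep_in(9,13)",
            "punct(9,14)"),
      list(tk(1, 7), tk(11, 11)),
      list(c("Plasminogen activator inhibitor 1 (PAI)", "vitronectin")),
      c("passive")),

    fx_case("table1_row03",
      "Binding|NN|binding of|IN G|NNP beta|NN gamma|NN to|TO Raf|NNP",
      "prep_of(1,5) prep_to(1,7) nn(5,3) nn(5,4)",
      list(tk(3, 5), tk(7, 7)),
      list(c("G beta gamma", "Raf")), c("nominalization")),

    fx_case("table1_row04",
      "Raf-1-|NNP|raf-1 ~binding|VBG|bind proteins|NNS|protein ~,|, Ras|NNP",
      "amod(3,2) nn(2,1) appos(3,5) punct(3,4)",
      list(list(text = "Raf-1"), tk(5, 5)),
      list(c("Raf-1", "Ras")), c("adjective", "appositive")),

    fx_case("table1_row05",
      paste("Shc|NNP ~,|, which|WDT specifically|RB binds|VBZ|bind the|DT",
            "SH2|NN domain|NN of|IN GRB2|NNP"),
      paste("rcmod(1,5) punct(1,2) nsubj(5,3) advmod(5,4) dobj(5,8)",
            "det(8,6) nn(8,7) prep_of(8,10)"),
      list(tk(1, 1), tk(10, 10)),
      list(c("Shc", "GRB2")), c("full-relative-clause", "part-whole")),

    fx_case("table1_row06",
      paste("Structure|NN of|IN ERK2|NNP bound|VBN|bind to|TO PEA-15|NNP",
            "reveals|VBZ|reveal a|DT mechanism|NN for|IN rapid|JJ release|NN",
            "of|IN activated|VBN|activate MAPK|NNP ~.|."),
      paste("nsubj(7,1) prep_of(1,3) vmod(3,4) prep_to(4,6) dobj(7,9)",
            "det(9,8) prep_for(9,12) amod(12,11) prep_of(12,15) amod(15,14)",
            "punct(7,16)"),
      list(tk(3, 3), tk(6, 6), tk(15, 15)),
      list(c("ERK2", "PEA-15")), c("reduced-relative-clause")),

    fx_case("table1_row07",
      paste("p53|NNP binds|VBZ|bind and|CC activates|VBZ|activate the|DT",
            "xeroderma|NN pigmentosum|NN DDB2|NNP gene|NN in|IN",
            "humans|NNS|human"),
      paste("nsubj(2,1) cc(2,3) conj_and(2,4) nsubj(4,1) dobj(2,9) dobj(4,9)",
            "det(9,5) nn(9,6) nn(9,7) nn(9,8) prep_in(2,11) prep_in(4,11)"),
      list(tk(1, 1), tk(6, 9)),
      list(c("p53", "xeroderma pigmentosum DDB2 gene")), c("coordination")),

    fx_case("table1_row08",
      paste("Histone|NNP deacetylase|NN 1|CD can|MD repress|VB",
            "transcription|NN by|IN binding|VBG|bind to|TO Sp1|NNP ~.|."),
      paste("nn(2,1) num(2,3) nsubj(5,2) aux(5,4) dobj(5,6) prepc_by(5,8)",
            "prep_to(8,10) punct(5,11)"),
      list(tk(1, 3), tk(10, 10)),
      list(c("Histone deacetylase 1", "Sp1")), c("null-argument")),

    fx_case("table1_row09",
      paste("CD5|NNP is|VBZ|be a|DT T-cell-specific|JJ antigen|NN which|WDT",
            "binds|VBZ|bind to|TO the|DT B-cell|NN antigen|NN CD72|NNP"),
      paste("nsubj(5,1) cop(5,2) det(5,3) amod(5,4) rcmod(5,7) nsubj(7,6)",
            "prep_to(7,12) det(12,9) nn(12,10) nn(12,11)"),
      list(tk(1, 1), tk(12, 12)),
      list(c("CD5", "CD72")), c("is-a", "full-relative-clause")),

    fx_case("table1_row10",
      paste("TPO|NNP binds|VBZ|bind and|CC activates|VBZ|activate its|PRP$",
            "receptor|NN ~,|, myeloproliferative|JJ leukemia|NN virus|NN",
            "receptor|NN"),
      paste("nsubj(2,1) cc(2,3) conj_and(2,4) nsubj(4,1) dobj(2,6) dobj(4,6)",
            "poss(6,5) appos(6,11) punct(6,7) amod(11,8) nn(11,9) nn(11,10)"),
      list(tk(1, 1), tk(8, 11)),
      list(c("TPO", "myeloproliferative leukemia virus receptor")),
      c("appositive", "coordination")),

    fx_case("table1_row11",
      paste("The|DT basic|JJ cleft|NN of|IN RPA70N|NNP binds|VBZ|bind",
            "multiple|JJ checkpoint|NN proteins|NNS|protein ~,|,",
            "including|VBG|include RAD9|NNP"),
      paste("det(3,1) amod(3,2) nsubj(6,3) prep_of(3,5) dobj(6,9) amod(9,7)",
            "nn(9,8) punct(9,10) prep_including(9,12)"),
      list(tk(5, 5), tk(12, 12)),
      list(c("RPA70N", "RAD9")), c("member-collection", "part-whole")),

    fx_case("table1_row12",
      paste("ARTS|NNP binds|VBZ|bind to|TO a|DT distinct|JJ domain|NN in|IN",
            "XIAP-BIR3|NNP"),
      "nsubj(2,1) prep_to(2,6) det(6,4) amod(6,5) prep_in(6,8)",
      list(tk(1, 1), tk(8, 8)),
      list(c("ARTS", "XIAP-BIR3")), c("part-whole")),

    fx_case("table1_row13",
      paste("TR6|NNP specifically|RB binds|VBZ|bind two|CD cellular|JJ",
            "ligands|NNS|ligand ~,|, LIGHT|NNP (|-LRB- ~herpes|NN virus|NN",
            "entry|NN mediator|NN (HVEM)-L|NN ~)|-RRB- and|CC Fas|NNP",
            "ligand|NN (|-LRB- ~FasL/CD95L|NNP ~)|-RRB-"),
      paste("nsubj(3,1) advmod(3,2) dobj(3,6) num(6,4) amod(6,5) punct(6,7)",
            "appos(6,8) appos(8,14) nn(14,10) nn(14,11) nn(14,12) nn(14,13)",
            "punct(8,9) punct(8,15) cc(8,16) conj_and(8,18) appos(18,20)",
            "nn(18,17) punct(18,19) punct(18,21)"),
      list(tk(1, 1), tk(8, 8), tk(10, 14), tk(17, 18), tk(20, 20)),
      list(c("TR6", "LIGHT"), c("TR6", "Fas ligand")),
      c("combination", "coordination", "appositive")),

    fx_case("fig1_active",
      "JAK2|NNP activates|VBZ|activate STAT1|NNP",
      "nsubj(2,1) dobj(2,3)",
      list(tk(1, 1), tk(3, 3)),
      list(c("JAK2", "STAT1")), c("active")),

    fx_case("fig1_passive",
      "STAT1|NNP is|VBZ|be activated|VBN|activate by|IN JAK2|NNP",
      "nsubjpass(3,1) auxpass(3,2) prep_by(3,5)",
      list(tk(1, 1), tk(5, 5)),
      list(c("JAK2", "STAT1")), c("passive")),

    fx_case("fig1_nominal",
      "Activation|NN|activation of|IN STAT1|NNP by|IN JAK2|NNP",
      "prep_of(1,3) prep_by(1,5)",
      list(tk(3, 3), tk(5, 5)),
      list(c("JAK2", "STAT1")), c("nominalization")),

    fx_case("kap_tap_s1",
      paste("Kap|NNP beta2B|NNP Is|VBZ|be Associated|VBN|associate with|IN",
            "TAP|NNP in|IN the|DT Presence|NN|presence of|IN RanGTP|NNP"),
      paste("nn(2,1) nsubjpass(4,2) auxpass(4,3) prep_with(4,6) prep_in(4,9)",
            "det(9,8) prep_of(9,11)"),
      list(tk(1, 2), tk(6, 6), tk(11, 11)),
      list(c("Kap beta2B", "TAP")), c("passive")),

    fx_case("kap_tap_s2",
      paste("The|DT data|NNS|datum presented|VBN|present support|VBP",
            "the|DT conclusion|NN that|IN Kap|NNP beta2B|NNP is|VBZ|be a|DT",
            "major|JJ carrier|NN for|IN export|NN of|IN cellular|JJ mRNA|NN",
            "and|CC TAP|NNP connects|VBZ|connect Kap|NNP beta2B|NNP to|TO",
            "the|DT mRNAs|NNS|mrna to|TO be|VB|be exported|VBN|export ~,|,",
            "whereas|IN the|DT direct|JJ interaction|NN of|IN TAP|NNP",
            "with|IN nucleoporins|NNS|nucleoporin allows|VBZ|allow lower|JJR",
            "rates|NNS|rate of|IN mRNA|NN export|NN ~.|."),
      paste("det(2,1) nsubj(4,2) vmod(2,3) det(6,5) dobj(4,6) mark(13,7)",
            "nsubj(13,9) cop(13,10) det(13,11) amod(13,12) ccomp(4,13)",
            "nn(9,8) prep_for(13,15) prep_of(15,18) amod(18,17) cc(13,19)",
            "conj_and(13,21) nsubj(21,20) dobj(21,23) nn(23,22) prep_to(21,26)",
            "det(26,25) vmod(26,29) aux(29,27) auxpass(29,28) punct(21,30)",
            "advcl(21,39) mark(39,31) nsubj(39,34) det(34,32) amod(34,33)",
            "prep_of(34,36) prep_with(34,38) dobj(39,41) amod(41,40)",
            "prep_of(41,44) nn(44,43) punct(4,45)"),
      list(tk(8, 9), tk(20, 20), tk(22, 23), tk(36, 36)),
      list(), character(0))
  )
}

fixture_env <- new.env(parent = emptyenv())

fixture_cases <- function() {
  if (is.null(fixture_env$cases)) {
    cases <- fixture_case_specs()
    names(cases) <- vapply(cases, `[[`, "", "case_id")
    # aliases: the ARTS sentence is Table 1 row 12; Fig 3 is the EDG of row 13
    cases[["arts"]] <- within_alias(cases[["table1_row12"]], "arts")
    cases[["fig3"]] <- within_alias(cases[["table1_row13"]], "fig3")
    fixture_env$cases <- cases
  }
  fixture_env$cases
}

within_alias <- function(case, new_id) {
  case$case_id <- new_id
  case$graph$sent_id <- new_id
  case
}

#' Available fixture case ids
#'
#' @return character vector of case ids accepted by [load_fixture()]
#' @export
fixture_ids <- function() {
  c(names(fixture_cases()), "kap_tap")
}

#' Load a fixture case
#'
#' Sentence cases return the hand-built parse, mentions and expected pairs
#' for one canonical construct (ids \code{table1_row01} ... \code{table1_row13},
#' \code{fig1_active}/\code{fig1_passive}/\code{fig1_nominal}, \code{arts},
#' \code{fig3}, \code{kap_tap_s1}, \code{kap_tap_s2}). The document case
#' \code{kap_tap} returns a two-sentence Results/Discussion
#' \code{bioc_document} with its per-sentence parses, exercising the trigger
#' co-occurrence passage rule.
#'
#' @param case_id fixture identifier
#' @return for sentence cases, a list with \code{case_id}, \code{sentence},
#'   \code{graph}, \code{mentions}, \code{expected_pairs},
#'   \code{construct_tags}; for \code{kap_tap}, a list with \code{doc},
#'   \code{parses} and \code{expected_pairs}
#' @export
load_fixture <- function(case_id) {
  if (case_id == "kap_tap") return(kap_tap_document())
  cases <- fixture_cases()
  if (!case_id %in% names(cases))
    stop("unknown fixture id '", case_id, "'; available: ",
         paste(fixture_ids(), collapse = ", "))
  cases[[case_id]]
}

kap_tap_document <- function() {
  s1 <- load_fixture("kap_tap_s1")
  s2 <- load_fixture("kap_tap_s2")
  doc <- bioc_document_from_parts(
    doc_id = "kap_tap",
    sections = list(
      list(name = "results", type_raw = "results",
           sentences = s1$sentence, mentions = list(s1$mentions)),
      list(name = "discussion", type_raw = "discussion",
           sentences = s2$sentence, mentions = list(s2$mentions))))
  list(case_id = "kap_tap", doc = doc, parses = list(s1$graph, s2$graph),
       expected_pairs = list(c("Kap beta2B", "TAP")))
}

#' Assemble a bioc_document from plain parts
#'
#' Convenience constructor used by fixtures and tests: sentences are given as
#' text (document offsets are computed, one space between sentences and
#' sections) and mentions in sentence-local coordinates.
#'
#' @param doc_id document identifier
#' @param sections list of lists with \code{name}, optional \code{type_raw},
#'   \code{sentences} (character vector) and optional \code{mentions} (list,
#'   parallel to \code{sentences}, of sentence-local mention data frames)
#' @return a \code{bioc_document}
#' @export
bioc_document_from_parts <- function(doc_id, sections) {
  out_sections <- list()
  mentions <- empty_mention_df()
  mentions$sentence_index <- integer(0)
  offset <- 0L
  index <- 0L
  mcount <- 0L
  for (sec in sections) {
    rows <- data.frame(text = character(), offset = integer(),
                       index = integer())
    sec_offset <- offset
    for (k in seq_along(sec$sentences)) {
      index <- index + 1L
      txt <- sec$sentences[[k]]
      rows <- rbind_df(rows, data.frame(text = txt, offset = offset,
                                        index = index))
      men <- if (!is.null(sec$mentions)) sec$mentions[[k]] else NULL
      if (!is.null(men) && nrow(men) > 0L) {
        men$start <- men$start + offset
        men$end <- men$end + offset
        men$sentence_index <- index
        men$mention_id <- paste0("m", mcount + seq_len(nrow(men)))
        mcount <- mcount + nrow(men)
        mentions <- rbind_df(mentions, men)
      }
      offset <- offset + nchar(txt) + 1L
    }
    out_sections[[length(out_sections) + 1L]] <-
      list(name = sec$name, type_raw = sec$type_raw %||% sec$name,
           offset = sec_offset, sentences = rows)
  }
  structure(list(doc_id = doc_id, sections = out_sections,
                 mentions = mentions),
            class = "bioc_document")
}

#' Fixture-backed parser adapter
#'
#' Returns an adapter function mapping known sentence texts to their stored
#' gold parses. Unknown sentences raise an explicit "no parse available"
#' error rather than returning a silently empty graph.
#'
#' @return a function \code{character(1) -> depgraph}
#' @export
fixture_parser <- function() {
  cases <- fixture_cases()
  tab <- list()
  for (case in cases) tab[[case$sentence]] <- case$graph
  function(sentence_text) {
    g <- tab[[sentence_text]]
    if (is.null(g))
      stop("no parse available for sentence: ", substr(sentence_text, 1, 60))
    g
  }
}

#' Export fixture sentence cases as a BioC collection
#'
#' Writes each requested sentence case as a one-sentence document with its
#' entity annotations, for end-to-end tests of the BioC pipeline.
#'
#' @param case_ids fixture ids (default: the 13 construct rows)
#' @param path output BioC XML path
#' @return invisibly, \code{path}
#' @export
export_fixture_collection <- function(case_ids = sprintf("table1_row%02d", 1:13),
                                      path) {
  docs <- lapply(case_ids, function(id) {
    case <- load_fixture(id)
    bioc_document_from_parts(id, list(list(
      name = "results", type_raw = "results",
      sentences = case$sentence, mentions = list(case$mentions))))
  })
  write_collection(docs, NULL, path)
}
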