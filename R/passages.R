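EVIDENCE_LEVELS <- c("direct", "technique", "trigger_cooccurrence")

#' PPI passage annotation
#'
#' One or more consecutive sentences flagged as PPI evidence, with the kind of
#' evidence (\code{direct}: a predicate-argument rule fired;
#' \code{technique}: an experimental-technique keyword co-occurs with a known
#' pair; \code{trigger_cooccurrence}: a PPI trigger co-occurs with a known
#' pair without a connecting EDG path) and a flag for passages likely to
#' report newly validated interactions.
#'
#' @param sentence_indices contiguous ascending integer vector of
#'   document-wide sentence indices
#' @param evidence one of \code{"direct"}, \code{"technique"},
#'   \code{"trigger_cooccurrence"}
#' @param pairs PPI-pair data frame backing the annotation
#' @param new_ppi logical flag, set by [flag_new_ppi()]
#' @return an object of class \code{passage_annotation}
#' @export
passage_annotation <- function(sentence_indices, evidence, pairs = NULL,
                               new_ppi = FALSE) {
  sentence_indices <- as.integer(sentence_indices)
  stopifnot(length(sentence_indices) > 0L,
            all(diff(sentence_indices) == 1L),
            evidence %in% EVIDENCE_LEVELS)
  if (is.null(pairs)) pairs <- empty_pair_df()
  if (evidence == "direct" && nrow(pairs) == 0L)
    stop("direct-evidence passage requires a non-empty pair list")
  structure(list(sentence_indices = sentence_indices, evidence = evidence,
                 pairs = pairs, new_ppi = isTRUE(new_ppi)),
            class = "passage_annotation")
}

#' @export
print.passage_annotation <- function(x, ...) {
  cat(sprintf("<passage sentences %s: %s, %d pair(s), new_ppi=%s>\n",
              paste(range(x$sentence_indices), collapse = "-"), x$evidence,
              nrow(x$pairs), x$new_ppi))
  invisible(x)
}

#' Build the document-wide known-pair index
#'
#' Maps each unique extracted pair (normalized, unordered) to its supporting
#' extractions. Normalization lowercases and strips hyphens/whitespace;
#' sentence-level matching additionally tolerates surface decoration
#' ("Flag-tagged STRAP" matches "STRAP") via substring containment of the
#' normalized names.
#'
#' @param pairs PPI-pair data frame from [extract_document()]
#' @return an object of class \code{known_pair_index}: list of entries with
#'   \code{norm_a}, \code{norm_b}, \code{name_a}, \code{name_b},
#'   \code{support} (the pair rows)
#' @export
known_pair_index <- function(pairs) {
  entries <- list()
  if (nrow(pairs) > 0L) {
    na <- normalize_name(pairs$name_a)
    nb <- normalize_name(pairs$name_b)
    key <- pair_key(na, nb)
    for (k in unique(key)) {
      rows <- pairs[key == k, , drop = FALSE]
      entries[[k]] <- list(norm_a = na[key == k][1], norm_b = nb[key == k][1],
                           name_a = rows$name_a[1], name_b = rows$name_b[1],
                           support = rows)
    }
  }
  structure(entries, class = "known_pair_index")
}

# Tolerant name match: containment of normalized names either way.
name_matches <- function(mention_norm, target_norm) {
  nzchar(mention_norm) & nzchar(target_norm) &
    (mapply(grepl, target_norm, mention_norm, MoreArgs = list(fixed = TRUE)) |
       mapply(grepl, mention_norm, target_norm, MoreArgs = list(fixed = TRUE)))
}

# Does sentence `index` of `doc` mention both members of a known-pair entry
# (with two distinct mentions)?
sentence_has_pair <- function(doc, index, entry) {
  m <- doc$mentions[doc$mentions$sentence_index == index, , drop = FALSE]
  if (nrow(m) < 2L) return(FALSE)
  norm <- normalize_name(m$text)
  ia <- which(name_matches(norm, entry$norm_a))
  ib <- which(name_matches(norm, entry$norm_b))
  for (a in ia) if (any(ib != a)) return(TRUE)
  FALSE
}

#' Select sentences with direct rule hits
#'
#' One \code{evidence = "direct"} annotation per sentence containing at least
#' one extracted PPI pair, carrying all pairs of that sentence.
#'
#' @param doc a \code{bioc_document}
#' @param pairs PPI-pair data frame for the document
#' @return list of [passage_annotation()]
#' @export
select_direct <- function(doc, pairs) {
  out <- list()
  for (i in sort(unique(pairs$sentence_index))) {
    out[[length(out) + 1L]] <- passage_annotation(
      i, "direct", pairs[pairs$sentence_index == i, , drop = FALSE])
  }
  out
}

#' Extend passages via experimental-technique keywords
#'
#' Annotates each sentence that mentions both members of a pair already known
#' to interact elsewhere in the article and contains one of the technique
#' keywords (case-insensitive, hyphen/space tolerant substring match).
#' Applies only to known pairs: this rule boosts passage recall, never the
#' set of interacting partners.
#'
#' @param doc a \code{bioc_document}
#' @param known a [known_pair_index()]
#' @param lexicon a [trigger_lexicon()]
#' @return list of [passage_annotation()] with \code{evidence = "technique"}
#' @export
extend_by_technique <- function(doc, known, lexicon = default_lexicon()) {
  out <- list()
  sents <- document_sentences(doc)
  kw <- gsub("[-[:space:]]+", "", lexicon$technique_keywords)
  for (i in sents$index) {
    txt <- gsub("[-[:space:]]+", "", tolower(sents$text[sents$index == i]))
    if (!any(vapply(kw, grepl, TRUE, x = txt, fixed = TRUE))) next
    hits <- Filter(function(e) sentence_has_pair(doc, i, e), unclass(known))
    if (length(hits) == 0L) next
    support <- do.call(rbind_df, lapply(hits, `[[`, "support"))
    out[[length(out) + 1L]] <- passage_annotation(i, "technique", support)
  }
  out
}

# Lowercased lemmas available for a sentence: from its EDG or parse when
# available, otherwise a whitespace/punctuation tokenization of the text.
sentence_lemmas <- function(doc, index, edgs) {
  g <- if (index <= length(edgs)) edgs[[index]] else NULL
  if (!is.null(g)) {
    if (inherits(g, "edg")) return(g$vertices$lemma)
    if (inherits(g, "depgraph")) return(g$tokens$lemma)
  }
  sents <- document_sentences(doc)
  txt <- sents$text[sents$index == index]
  tolower(strsplit(txt, "[^A-Za-z0-9-]+")[[1]])
}

#' Extend passages via trigger and known-pair co-occurrence
#'
#' Annotates each sentence that mentions both members of a known pair plus a
#' PPI trigger lemma (any lexicon class except the technique keywords) but
#' where the predicate-argument rules extracted nothing for that pair — the
#' case where a complicated sentence continues the topic of an interaction
#' established elsewhere.
#'
#' @param doc a \code{bioc_document}
#' @param known a [known_pair_index()]
#' @param lexicon a [trigger_lexicon()]
#' @param edgs list (indexed by sentence) of [edg] or [depgraph()] used for
#'   lemma lookup; sentences without one fall back to a plain tokenization
#' @return list of [passage_annotation()] with
#'   \code{evidence = "trigger_cooccurrence"}
#' @export
extend_by_trigger <- function(doc, known, lexicon = default_lexicon(),
                              edgs = list()) {
  out <- list()
  sents <- document_sentences(doc)
  for (i in sents$index) {
    lem <- sentence_lemmas(doc, i, edgs)
    if (!any(!is.na(trigger_base(lem, lexicon)))) next
    hits <- Filter(function(e) {
      if (!sentence_has_pair(doc, i, e)) return(FALSE)
      # skip pairs the rules already extracted in this very sentence
      !any(e$support$sentence_index == i)
    }, unclass(known))
    if (length(hits) == 0L) next
    support <- do.call(rbind_df, lapply(hits, `[[`, "support"))
    out[[length(out) + 1L]] <- passage_annotation(i, "trigger_cooccurrence",
                                                  support)
  }
  out
}

#' Merge annotations on consecutive sentences into passages
#'
#' Annotations whose sentence runs are adjacent (or overlapping) within the
#' same section merge into one passage: sentence indices united, pair lists
#' united, and the strongest evidence label retained
#' (direct > technique > trigger_cooccurrence). Every returned passage covers
#' a maximal run of consecutive annotated sentences.
#'
#' @param annotations list of [passage_annotation()]
#' @param doc the \code{bioc_document} the annotations belong to (supplies
#'   section boundaries)
#' @return list of merged [passage_annotation()]
#' @export
assemble_passages <- function(annotations, doc) {
  if (length(annotations) == 0L) return(list())
  sents <- document_sentences(doc)
  section_of <- stats::setNames(sents$section_id, sents$index)
  firsts <- vapply(annotations, function(a) min(a$sentence_indices), 1L)
  annotations <- annotations[order(firsts)]
  merged <- list()
  cur <- NULL
  for (a in annotations) {
    if (!is.null(cur) &&
        min(a$sentence_indices) <= max(cur$sentence_indices) + 1L &&
        section_of[[as.character(min(a$sentence_indices))]] ==
          section_of[[as.character(max(cur$sentence_indices))]]) {
      idx <- sort(unique(c(cur$sentence_indices, a$sentence_indices)))
      ev <- EVIDENCE_LEVELS[min(match(c(cur$evidence, a$evidence),
                                      EVIDENCE_LEVELS))]
      pairs <- dedup_df(rbind_df(cur$pairs, a$pairs),
                        c("mention_a", "mention_b", "sentence_index"))
      cur <- passage_annotation(idx, ev, pairs)
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- a
    }
  }
  merged[[length(merged) + 1L]] <- cur
  merged
}

# For each section, which major section does it belong to? Subsection titles
# and figure captions inherit the most recent major section seen in document
# order, so "fig-caption after results" counts as a Results figure caption.
section_context <- function(doc) {
  major <- c("title", "abstract", "results", "discussion", "methods", "other")
  ctx <- character(length(doc$sections))
  cur <- "other"
  for (si in seq_along(doc$sections)) {
    nm <- doc$sections[[si]]$name
    if (nm %in% major) cur <- nm
    ctx[si] <- cur
  }
  ctx
}

#' Flag passages likely to report newly validated PPIs
#'
#' A passage is flagged \code{new_ppi = TRUE} when it lies in the Results
#' section (or, for documents without a Results section, in the Abstract), in
#' a Results subsection title or Results figure caption, or when one of its
#' sentences begins (after optional quotes/parentheses, case-insensitive)
#' with an experimental-goal phrase such as "to investigate". Pure function
#' of section labels and sentence text; re-running it is idempotent.
#'
#' @param passages list of [passage_annotation()]
#' @param doc the \code{bioc_document}
#' @param lexicon a [trigger_lexicon()] (supplies the goal-phrase list)
#' @return the passages with \code{new_ppi} set
#' @export
flag_new_ppi <- function(passages, doc, lexicon = default_lexicon()) {
  sents <- document_sentences(doc)
  ctx <- section_context(doc)
  has_results <- any(vapply(doc$sections, function(s) s$name == "results",
                            TRUE))
  goal_re <- paste0("^[\"'([:space:]]*(",
                    paste(gsub(" ", "[[:space:]]+", lexicon$goal_phrases),
                          collapse = "|"), ")\\b")
  lapply(passages, function(p) {
    rows <- sents[sents$index %in% p$sentence_indices, , drop = FALSE]
    sec_names <- rows$section
    sec_ctx <- ctx[rows$section_id]
    flag <-
      any(sec_names == "results") ||
      (!has_results && any(sec_names == "abstract")) ||
      any(sec_names == "subsection-title" & sec_ctx == "results") ||
      any(sec_names == "fig-caption" & sec_ctx == "results") ||
      any(grepl(goal_re, rows$text, ignore.case = TRUE))
    p$new_ppi <- flag
    p
  })
}

#' Detect PPI passages in one document
#'
#' Full passage pipeline: extract pairs sentence by sentence, select direct
#' sentences, extend with the technique and trigger co-occurrence rules over
#' the document-wide known-pair index, merge consecutive annotations into
#' passages, and flag likely new-PPI passages.
#'
#' @param doc a \code{bioc_document}
#' @param parses list of [depgraph()] indexed by sentence index
#' @param lexicon a [trigger_lexicon()]
#' @return list of [passage_annotation()]
#' @export
detect_passages <- function(doc, parses, lexicon = default_lexicon()) {
  pairs <- extract_document(doc, parses, lexicon)
  direct <- select_direct(doc, pairs)
  known <- known_pair_index(pairs)
  tech <- extend_by_technique(doc, known, lexicon)
  trig <- extend_by_trigger(doc, known, lexicon, edgs = parses)
  # a sentence already carrying direct evidence never needs extension
  direct_idx <- vapply(direct, function(a) a$sentence_indices[1], 1L)
  ext <- Filter(function(a) !(a$sentence_indices[1] %in% direct_idx),
                c(tech, trig))
  anns <- c(direct, ext)
  if (length(anns) == 0L) return(list())
  flag_new_ppi(assemble_passages(anns, doc), doc, lexicon)
}

#' Write passages as TSV
#'
#' @param passages list of [passage_annotation()]
#' @param doc the \code{bioc_document}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_passages_tsv <- function(passages, doc, path) {
  rows <- lapply(passages, function(p) data.frame(
    doc_id = doc$doc_id,
    first_sentence = min(p$sentence_indices),
    last_sentence = max(p$sentence_indices),
    evidence = p$evidence,
    new_ppi = p$new_ppi,
    n_pairs = nrow(p$pairs)))
  utils::write.table(do.call(rbind_df, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
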