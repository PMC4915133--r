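#' Default mapping from BioC passage types to section names
#'
#' BioC encodes section information as passage infons whose vocabulary varies
#' by corpus. This table-driven mapping normalizes common values onto the
#' controlled vocabulary \code{title}, \code{abstract}, \code{results},
#' \code{discussion}, \code{methods}, \code{fig-caption},
#' \code{subsection-title}, \code{other}; unmapped values become
#' \code{other}.
#'
#' @return named character vector (lowercased raw type -> section name)
#' @export
default_section_map <- function() {
  c(title = "title", "front" = "title",
    abstract = "abstract", "abstract_title_1" = "abstract",
    results = "results", result = "results", "results_title_1" = "subsection-title",
    "subsection-title" = "subsection-title", "title_1" = "subsection-title",
    "title_2" = "subsection-title",
    discussion = "discussion", "discuss" = "discussion",
    methods = "methods", method = "methods", "materials and methods" = "methods",
    "fig-caption" = "fig-caption", fig = "fig-caption", figure = "fig-caption",
    "fig_caption" = "fig-caption", "fig_title_caption" = "fig-caption",
    paragraph = "other", ref = "other")
}

map_section <- function(raw, section_map) {
  key <- tolower(raw)
  unname(ifelse(key %in% names(section_map), section_map[key], "other"))
}

bioc_infons <- function(node) {
  inf <- xml2::xml_find_all(node, "./infon")
  stats::setNames(xml2::xml_text(inf), xml2::xml_attr(inf, "key"))
}

infon_get <- function(inf, key) {
  if (key %in% names(inf)) inf[[key]] else NULL
}

read_bioc_annotations <- function(nodes, entity_types) {
  out <- empty_mention_df()
  for (a in nodes) {
    inf <- bioc_infons(a)
    typ <- infon_get(inf, "type") %||% ""
    if (!(tolower(typ) %in% tolower(entity_types))) next
    loc <- xml2::xml_find_first(a, "./location")
    off <- as.integer(xml2::xml_attr(loc, "offset"))
    len <- as.integer(xml2::xml_attr(loc, "length"))
    out <- rbind_df(out, data.frame(
      mention_id = xml2::xml_attr(a, "id"),
      text = xml2::xml_text(xml2::xml_find_first(a, "./text")),
      start = off, end = off + len,
      entity_type = tolower(typ)))
  }
  out
}

#' Read a BioC XML collection
#'
#' Returns one \code{bioc_document} per BioC document: sections (one per
#' passage, with the passage type mapped onto a controlled section
#' vocabulary), sentence-level text with 0-based character offsets, and
#' gene/protein entity-mention annotations resolved to sentences. Mentions
#' whose spans cross sentence boundaries are dropped with a warning; an
#' annotation offset outside the document text is a validation error.
#'
#' @param path path to a BioC XML file
#' @param entity_types annotation infon \code{type} values (case-insensitive)
#'   accepted as entity mentions
#' @param section_map named character vector mapping raw passage types to
#'   section names; see [default_section_map()]
#' @return list of \code{bioc_document}
#' @export
read_collection <- function(path, entity_types = c("gene", "protein"),
                            section_map = default_section_map()) {
  xml <- xml2::read_xml(path)
  docs <- xml2::xml_find_all(xml, "//document")
  lapply(docs, function(dnode) {
    doc_id <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
    sections <- list()
    mentions <- empty_mention_df()
    sent_rows <- data.frame(text = character(), offset = integer(),
                            section = integer())
    for (pnode in xml2::xml_find_all(dnode, "./passage")) {
      inf <- bioc_infons(pnode)
      raw <- infon_get(inf, "type") %||% infon_get(inf, "section_type") %||%
        infon_get(inf, "section") %||% "other"
      p_off <- as.integer(xml2::xml_text(xml2::xml_find_first(pnode, "./offset")))
      snodes <- xml2::xml_find_all(pnode, "./sentence")
      if (length(snodes) > 0L) {
        s_off <- vapply(snodes, function(s)
          as.integer(xml2::xml_text(xml2::xml_find_first(s, "./offset"))), 1L)
        s_txt <- vapply(snodes, function(s)
          xml2::xml_text(xml2::xml_find_first(s, "./text")), "")
        for (s in snodes)
          mentions <- rbind_df(mentions, read_bioc_annotations(
            xml2::xml_find_all(s, "./annotation"), entity_types))
      } else {
        s_off <- p_off
        s_txt <- xml2::xml_text(xml2::xml_find_first(pnode, "./text"))
        if (is.na(s_txt)) next
      }
      mentions <- rbind_df(mentions, read_bioc_annotations(
        xml2::xml_find_all(pnode, "./annotation"), entity_types))
      si <- length(sections) + 1L
      sections[[si]] <- list(name = map_section(raw, section_map),
                             type_raw = raw, offset = p_off)
      sent_rows <- rbind_df(sent_rows, data.frame(text = s_txt, offset = s_off,
                                                  section = si))
    }
    if (nrow(sent_rows) > 0L) {
      if (is.unsorted(sent_rows$offset, strictly = TRUE) &&
          nrow(sent_rows) > 1L)
        stop("document ", doc_id, ": sentence offsets not strictly ascending")
      ends <- sent_rows$offset + nchar(sent_rows$text)
      if (nrow(sent_rows) > 1L &&
          any(sent_rows$offset[-1] < ends[-length(ends)]))
        stop("document ", doc_id, ": overlapping sentence spans")
    }
    sent_rows$index <- seq_len(nrow(sent_rows))
    for (si in seq_along(sections))
      sections[[si]]$sentences <-
        sent_rows[sent_rows$section == si, c("text", "offset", "index"),
                  drop = FALSE]

    # resolve mentions to sentences
    doc_end <- if (nrow(sent_rows) > 0L)
      max(sent_rows$offset + nchar(sent_rows$text)) else 0L
    if (nrow(mentions) > 0L) {
      mentions$mention_id <- ifelse(is.na(mentions$mention_id),
                                    paste0("m", seq_len(nrow(mentions))),
                                    mentions$mention_id)
      sentence_index <- integer(nrow(mentions))
      keep <- rep(TRUE, nrow(mentions))
      for (i in seq_len(nrow(mentions))) {
        m <- mentions[i, ]
        if (m$start < 0L || m$end > doc_end)
          stop("document ", doc_id, ": annotation ", m$mention_id,
               " offset [", m$start, ",", m$end, ") outside document text")
        hit <- which(sent_rows$offset <= m$start &
                       m$end <= sent_rows$offset + nchar(sent_rows$text))
        if (length(hit) == 0L) {
          warning("document ", doc_id, ": annotation ", m$mention_id,
                  " crosses sentence boundaries; dropped")
          keep[i] <- FALSE
          next
        }
        sentence_index[i] <- sent_rows$index[hit[1]]
        got <- substr(sent_rows$text[hit[1]],
                      m$start - sent_rows$offset[hit[1]] + 1L,
                      m$end - sent_rows$offset[hit[1]])
        if (!is.na(m$text) && nzchar(m$text) && got != m$text)
          stop("document ", doc_id, ": annotation ", m$mention_id,
               " text '", m$text, "' does not match document substring '",
               got, "'")
      }
      mentions$sentence_index <- sentence_index
      mentions <- mentions[keep, , drop = FALSE]
      rownames(mentions) <- NULL
    } else {
      mentions$sentence_index <- integer(0)
    }
    structure(list(doc_id = doc_id, sections = sections, mentions = mentions),
              class = "bioc_document")
  })
}

#' @export
print.bioc_document <- function(x, ...) {
  cat(sprintf("<bioc_document %s: %d sections, %d sentences, %d mentions>\n",
              x$doc_id, length(x$sections), nrow(document_sentences(x)),
              nrow(x$mentions)))
  invisible(x)
}

#' All sentences of a document
#'
#' @param doc a \code{bioc_document}
#' @return data frame with columns \code{text}, \code{offset}, \code{index},
#'   \code{section} (mapped name), \code{section_id}
#' @export
document_sentences <- function(doc) {
  out <- data.frame(text = character(), offset = integer(), index = integer(),
                    section = character(), section_id = integer())
  for (si in seq_along(doc$sections)) {
    s <- doc$sections[[si]]
    if (nrow(s$sentences) == 0L) next
    out <- rbind_df(out, data.frame(s$sentences, section = s$name,
                                    section_id = si))
  }
  out[order(out$index), , drop = FALSE]
}

#' Mentions of one sentence, in sentence-local coordinates
#'
#' @param doc a \code{bioc_document}
#' @param index document-wide sentence index
#' @return mention data frame with \code{start}/\code{end} relative to the
#'   sentence
#' @export
sentence_mentions <- function(doc, index) {
  sents <- document_sentences(doc)
  off <- sents$offset[sents$index == index]
  m <- doc$mentions[doc$mentions$sentence_index == index, , drop = FALSE]
  if (nrow(m) > 0L) {
    m$start <- m$start - off
    m$end <- m$end - off
  }
  rownames(m) <- NULL
  m[, c("mention_id", "text", "start", "end", "entity_type"), drop = FALSE]
}

pairs_infon <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return("")
  paste(sprintf("%s|%s|%s|%s", pairs$mention_a, pairs$mention_b,
                pairs$trigger, pairs$rule_id), collapse = ";")
}

#' Write a BioC XML collection with PPI passage annotations
#'
#' Re-emits documents (sections, sentences, entity mentions) bit-exactly and
#' attaches one annotation element per [passage_annotation()], carrying the
#' covered character range and infons \code{type=PPI_passage},
#' \code{evidence}, \code{new_ppi} and \code{pairs}
#' (semicolon-separated \code{mentionA|mentionB|trigger|rule}). Reading the
#' file back with [read_collection()] reproduces the input documents.
#'
#' @param documents list of \code{bioc_document}
#' @param annotations list (parallel to \code{documents}) of lists of
#'   [passage_annotation()]; may be \code{NULL}
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
write_collection <- function(documents, annotations = NULL, path) {
  if (inherits(documents, "bioc_document")) documents <- list(documents)
  if (is.null(annotations)) annotations <- vector("list", length(documents))
  stopifnot(length(annotations) == length(documents))
  # validate before any file is written
  for (di in seq_along(documents)) {
    sents <- document_sentences(documents[[di]])
    for (ann in annotations[[di]]) {
      bad <- setdiff(ann$sentence_indices, sents$index)
      if (length(bad) > 0L)
        stop("document ", documents[[di]]$doc_id,
             ": passage annotation references unknown sentence index ",
             paste(bad, collapse = ", "))
    }
  }
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", "edgppi")
  xml2::xml_add_child(root, "date", format(Sys.Date(), "%Y-%m-%d"))
  xml2::xml_add_child(root, "key", "edgppi.key")
  ann_counter <- 0L
  for (di in seq_along(documents)) {
    doc <- documents[[di]]
    dnode <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(dnode, "id", doc$doc_id)
    sents <- document_sentences(doc)
    for (si in seq_along(doc$sections)) {
      sec <- doc$sections[[si]]
      pnode <- xml2::xml_add_child(dnode, "passage")
      inf <- xml2::xml_add_child(pnode, "infon", sec$type_raw)
      xml2::xml_set_attr(inf, "key", "type")
      xml2::xml_add_child(pnode, "offset", as.character(sec$offset))
      for (k in seq_len(nrow(sec$sentences))) {
        srow <- sec$sentences[k, ]
        snode <- xml2::xml_add_child(pnode, "sentence")
        xml2::xml_add_child(snode, "offset", as.character(srow$offset))
        xml2::xml_add_child(snode, "text", srow$text)
        men <- doc$mentions[doc$mentions$sentence_index == srow$index, ,
                            drop = FALSE]
        for (mi in seq_len(nrow(men))) {
          m <- men[mi, ]
          anode <- xml2::xml_add_child(snode, "annotation")
          xml2::xml_set_attr(anode, "id", m$mention_id)
          i2 <- xml2::xml_add_child(anode, "infon", m$entity_type)
          xml2::xml_set_attr(i2, "key", "type")
          loc <- xml2::xml_add_child(anode, "location")
          xml2::xml_set_attr(loc, "offset", as.character(m$start))
          xml2::xml_set_attr(loc, "length", as.character(m$end - m$start))
          xml2::xml_add_child(anode, "text", m$text)
        }
      }
      # passage annotations whose first sentence lies in this section
      for (ann in annotations[[di]]) {
        first <- min(ann$sentence_indices)
        if (!(first %in% sec$sentences$index)) next
        cov <- sents[sents$index %in% ann$sentence_indices, , drop = FALSE]
        off0 <- min(cov$offset)
        len <- max(cov$offset + nchar(cov$text)) - off0
        ann_counter <- ann_counter + 1L
        anode <- xml2::xml_add_child(pnode, "annotation")
        xml2::xml_set_attr(anode, "id", paste0("ppi", ann_counter))
        for (kv in list(c("type", "PPI_passage"),
                        c("evidence", ann$evidence),
                        c("new_ppi", tolower(as.character(isTRUE(ann$new_ppi)))),
                        c("pairs", pairs_infon(ann$pairs)))) {
          i2 <- xml2::xml_add_child(anode, "infon", kv[[2]])
          xml2::xml_set_attr(i2, "key", kv[[1]])
        }
        loc <- xml2::xml_add_child(anode, "location")
        xml2::xml_set_attr(loc, "offset", as.character(off0))
        xml2::xml_set_attr(loc, "length", as.character(len))
        xml2::xml_add_child(anode, "text",
                            paste(cov$text, collapse = " "))
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
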