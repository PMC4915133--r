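#' Dependency graph of one sentence
#'
#' A \code{depgraph} bundles the tokens of one sentence with labeled directed
#' syntactic edges (Stanford typed-dependency names). Token character spans are
#' sentence-local, 0-based and half-open. Graphs read from basic (uncollapsed)
#' parses carry \code{normalized = FALSE} until [normalize_deps()] collapses
#' prepositions and propagates dependencies across conjuncts
#' (CCProcessed-style).
#'
#' @param tokens data frame with columns \code{index} (1-based token position),
#'   \code{text}, \code{lemma} (lowercase), \code{pos} (Penn tag),
#'   \code{start}, \code{end} (sentence-local half-open character span)
#' @param edges data frame with columns \code{label}, \code{gov}, \code{dep}
#'   (token indices)
#' @param normalized logical; \code{TRUE} if the graph is already in
#'   collapsed-and-propagated form
#' @param sent_id optional sentence identifier
#' @param text optional original sentence text
#' @return an object of class \code{depgraph}
#' @export
depgraph <- function(tokens, edges, normalized = FALSE, sent_id = NA_character_,
                     text = NA_character_) {
  tokens <- as.data.frame(tokens)
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) edges <- empty_edge_df()
  stopifnot(all(c("index", "text", "lemma", "pos", "start", "end") %in% names(tokens)),
            all(c("label", "gov", "dep") %in% names(edges)))
  if (anyDuplicated(tokens$index)) stop("duplicate token indices")
  tokens$lemma <- tolower(tokens$lemma)
  bad <- setdiff(c(edges$gov, edges$dep), tokens$index)
  if (length(bad) > 0L)
    stop("edge endpoint not among token indices: ", paste(bad, collapse = ", "))
  if (any(edges$gov == edges$dep)) stop("self-loop edge (governor equals dependent)")
  structure(list(tokens = tokens, edges = edges,
                 normalized = isTRUE(normalized),
                 sent_id = sent_id, text = text),
            class = "depgraph")
}

#' @export
print.depgraph <- function(x, ...) {
  cat(sprintf("<depgraph%s: %d tokens, %d edges, normalized=%s>\n",
              if (is.na(x$sent_id)) "" else paste0(" ", x$sent_id),
              nrow(x$tokens), nrow(x$edges), x$normalized))
  invisible(x)
}

# Labels onto which conjunct propagation duplicates dependencies. Restricting
# to the argument-bearing set mirrors the CCProcessed behaviour the extraction
# rules rely on and avoids pathological duplication of modifiers.
ARG_BEARING_LABELS <- c("nsubj", "nsubjpass", "dobj", "agent")

is_arg_bearing <- function(label) {
  label %in% ARG_BEARING_LABELS | startsWith(label, "prep_")
}

is_collapsed_label <- function(label) {
  startsWith(label, "prep_") | startsWith(label, "prepc_") |
    startsWith(label, "conj_")
}

#' Collapse prepositions and propagate conjunct dependencies
#'
#' Transforms a basic Stanford-style dependency graph into collapsed and
#' propagated form: \code{prep(g, p) + pobj(p, d)} becomes
#' \code{prep_<lemma(p)>(g, d)} (and \code{pcomp} chains become
#' \code{prepc_*}); an \code{agent(g, p) + pobj(p, d)} chain becomes
#' \code{agent(g, d)}; and for every \code{conj_*(a, b)} edge, dependencies of
#' \code{a} with an argument-bearing label (nsubj, nsubjpass, dobj, agent,
#' prep_*) are duplicated onto \code{b} in the same role. Vertices and token
#' spans are never changed; the operation is idempotent.
#'
#' @param graph a [depgraph()]
#' @return the normalized \code{depgraph} (\code{normalized = TRUE})
#' @export
normalize_deps <- function(graph) {
  stopifnot(inherits(graph, "depgraph"))
  if (graph$normalized) return(graph)
  edges <- graph$edges
  lemma_of <- stats::setNames(graph$tokens$lemma, graph$tokens$index)

  consumed <- rep(FALSE, nrow(edges))
  new_edges <- empty_edge_df()
  prep_idx <- which(edges$label %in% c("prep", "agent"))
  for (i in prep_idx) {
    p <- edges$dep[i]
    comp <- which((edges$label == "pobj" | edges$label == "pcomp") & edges$gov == p)
    for (j in comp) {
      lab <- if (edges$label[i] == "agent") {
        "agent"
      } else if (edges$label[j] == "pcomp") {
        paste0("prepc_", lemma_of[[as.character(p)]])
      } else {
        paste0("prep_", lemma_of[[as.character(p)]])
      }
      new_edges <- rbind_df(new_edges,
                            data.frame(label = lab, gov = edges$gov[i],
                                       dep = edges$dep[j]))
      consumed[j] <- TRUE
    }
    if (length(comp) > 0L) consumed[i] <- TRUE
  }
  # Orphaned prep/pobj/pcomp edges (no completing chain) are dropped so that no
  # bare case-marking edges survive normalization.
  consumed <- consumed | edges$label %in% c("prep", "pobj", "pcomp")
  edges <- rbind_df(edges[!consumed, , drop = FALSE], new_edges)
  edges <- dedup_df(edges, c("label", "gov", "dep"))

  # Conjunct propagation to fixpoint.
  repeat {
    conj <- edges[startsWith(edges$label, "conj_"), , drop = FALSE]
    added <- FALSE
    for (i in seq_len(nrow(conj))) {
      a <- conj$gov[i]; b <- conj$dep[i]
      gov_side <- edges[edges$gov == a & is_arg_bearing(edges$label) &
                          edges$dep != b, , drop = FALSE]
      dep_side <- edges[edges$dep == a & is_arg_bearing(edges$label) &
                          edges$gov != b, , drop = FALSE]
      cand <- rbind_df(
        if (nrow(gov_side)) data.frame(label = gov_side$label, gov = b,
                                       dep = gov_side$dep) else empty_edge_df(),
        if (nrow(dep_side)) data.frame(label = dep_side$label,
                                       gov = dep_side$gov, dep = b)
        else empty_edge_df())
      if (nrow(cand) > 0L) {
        merged <- dedup_df(rbind_df(edges, cand), c("label", "gov", "dep"))
        if (nrow(merged) > nrow(edges)) {
          edges <- merged
          added <- TRUE
        }
      }
    }
    if (!added) break
  }

  graph$edges <- edges
  graph$normalized <- TRUE
  graph
}

# ---------------------------------------------------------------------------
# CoNLL-U ingestion

# Fixed UD -> Stanford-dependencies label translation. UD obl/nmod relations
# are re-expressed as raw prep/pobj chains using the dependent's case marker so
# that normalize_deps() collapses them into prep_<lemma> edges.
UD_LABEL_MAP <- c(
  "nsubj:pass" = "nsubjpass", obj = "dobj", "aux:pass" = "auxpass",
  "acl:relcl" = "rcmod", acl = "vmod", compound = "nn", nummod = "num",
  appos = "appos", nsubj = "nsubj", iobj = "iobj", det = "det", amod = "amod",
  advmod = "advmod", aux = "aux", cop = "cop", mark = "mark", cc = "cc",
  punct = "punct", ccomp = "ccomp", xcomp = "xcomp", advcl = "advcl",
  dep = "dep", "det:predet" = "predet", "compound:prt" = "prt",
  expl = "expl", csubj = "csubj", parataxis = "parataxis"
)

map_upos <- function(upos) {
  m <- c(NOUN = "NN", PROPN = "NNP", VERB = "VB", ADJ = "JJ", ADV = "RB",
         ADP = "IN", DET = "DT", NUM = "CD", PRON = "PRP", CCONJ = "CC",
         SCONJ = "IN", PART = "RP", PUNCT = ".", AUX = "MD", SYM = "SYM",
         INTJ = "UH", X = "XX")
  out <- unname(m[upos])
  out[is.na(out)] <- "XX"
  out
}

token_spans <- function(forms, text) {
  start <- integer(length(forms))
  end <- integer(length(forms))
  if (is.na(text)) text <- paste(forms, collapse = " ")
  pos <- 1L
  for (i in seq_along(forms)) {
    hit <- regexpr(forms[i], substring(text, pos), fixed = TRUE)
    if (hit < 0L) stop("token '", forms[i], "' not found in sentence text")
    start[i] <- pos + as.integer(hit) - 2L  # 0-based
    end[i] <- start[i] + nchar(forms[i])
    pos <- end[i] + 1L
  }
  data.frame(start = start, end = end)
}

check_tree <- function(head, sent_label) {
  n <- length(head)
  if (sum(head == 0L) != 1L)
    stop("sentence ", sent_label, ": expected exactly one root, found ",
         sum(head == 0L))
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (head[j] != 0L) {
      if (seen[j]) stop("sentence ", sent_label, ": cyclic head chain at token ", i)
      seen[j] <- TRUE
      j <- head[j]
    }
  }
}

#' Read dependency graphs from a CoNLL-U file
#'
#' One [depgraph()] per sentence block. Universal Dependencies labels are
#' mapped to Stanford-style names via a fixed translation table
#' (\code{nsubj:pass} to \code{nsubjpass}, \code{obj} to \code{dobj},
#' \code{acl:relcl} to \code{rcmod}, \code{acl} to \code{vmod},
#' \code{compound} to \code{nn}, \code{conj} to \code{conj_<coordinator
#' lemma>}); \code{obl}/\code{nmod} plus their \code{case} dependent are
#' re-expressed as raw \code{prep}/\code{pobj} chains, which
#' [normalize_deps()] collapses into \code{prep_*} edges. Unmapped labels pass
#' through with an \code{other:} prefix. Graphs are returned with
#' \code{normalized = FALSE}.
#'
#' @param path path to a CoNLL-U file
#' @return list of \code{depgraph}
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0L]
  out <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    sent_id <- sub("^# sent_id = ", "", grep("^# sent_id = ", b, value = TRUE)[1])
    if (is.na(sent_id) || identical(sent_id, character(0))) sent_id <- paste0("s", bi)
    text <- sub("^# text = ", "", grep("^# text = ", b, value = TRUE)[1])
    rows <- b[!startsWith(b, "#")]
    fields <- strsplit(rows, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) grepl("^[0-9]+$", f[[1]]), TRUE)
    fields <- fields[keep]
    n <- length(fields)
    if (n == 0L) next
    get <- function(k) vapply(fields, function(f) f[[k]], "")
    id <- as.integer(get(1)); form <- get(2); lemma <- get(3)
    upos <- get(4); xpos <- get(5)
    head <- suppressWarnings(as.integer(get(7))); deprel <- get(8)
    if (anyNA(head)) stop("sentence ", bi, ": non-integer HEAD field")
    check_tree(head, bi)
    pos <- ifelse(xpos == "_" | xpos == "", map_upos(upos), xpos)
    lemma <- ifelse(lemma == "_" | lemma == "", tolower(form), tolower(lemma))
    sp <- token_spans(form, if (length(text)) text else NA_character_)
    tokens <- data.frame(index = id, text = form, lemma = lemma, pos = pos,
                         start = sp$start, end = sp$end)

    case_of <- integer(0)  # dependent token -> its case marker token
    ci <- which(deprel == "case")
    case_map <- stats::setNames(id[ci], head[ci])
    used_case <- integer(0)
    cc_map <- stats::setNames(id[deprel == "cc"], head[deprel == "cc"])

    lab <- character(0); gov <- integer(0); dep <- integer(0)
    add <- function(l, g, d) {
      lab <<- c(lab, l); gov <<- c(gov, g); dep <<- c(dep, d)
    }
    for (i in seq_len(n)) {
      if (head[i] == 0L) next
      d <- deprel[i]
      base <- sub(":.*$", "", d)
      if (d %in% names(UD_LABEL_MAP)) {
        add(UD_LABEL_MAP[[d]], head[i], id[i])
      } else if (base %in% c("obl", "nmod")) {
        ck <- as.character(id[i])
        if (ck %in% names(case_map)) {
          p <- case_map[[ck]]
          add("prep", head[i], p)
          add("pobj", p, id[i])
          used_case <- c(used_case, p)
        } else {
          add(paste0("other:", d), head[i], id[i])
        }
      } else if (base == "conj") {
        ck <- as.character(id[i])
        coord <- if (ck %in% names(cc_map)) lemma[id == cc_map[[ck]]] else "and"
        add(paste0("conj_", coord), head[i], id[i])
      } else if (d == "case") {
        # consumed by an obl/nmod chain, or emitted below as other:case
      } else if (d == "cc") {
        add("cc", head[i], id[i])
      } else if (base %in% names(UD_LABEL_MAP)) {
        add(UD_LABEL_MAP[[base]], head[i], id[i])
      } else {
        add(paste0("other:", d), head[i], id[i])
      }
    }
    # case markers not consumed by an obl/nmod chain
    for (i in which(deprel == "case")) {
      if (!(id[i] %in% used_case)) add("other:case", head[i], id[i])
    }
    edges <- data.frame(label = lab, gov = gov, dep = dep)
    out[[length(out) + 1L]] <- depgraph(tokens, edges, normalized = FALSE,
                                        sent_id = sent_id, text = text %||% NA_character_)
  }
  out
}

# ---------------------------------------------------------------------------
# stanford-deps text format
#
# One sentence per blank-line-separated block:
#   # sent_id = <id>          (optional)
#   # text = <sentence text>  (optional; used for token spans)
#   # normalized = true|false (optional; explicit normalization flag)
#   <index>\t<text>\t<lemma>\t<pos>[\t<start>\t<end>]   token header lines
#   rel(word-GOV, word-DEP)                             edge lines
# The word part before "-<idx>" in edge lines is decorative; only the indices
# are read.

#' Read dependency graphs from stanford-deps text
#'
#' Parses the repository's line-based dependency format (see the package
#' vignette): a token header block followed by \code{rel(gov-i, dep-j)} lines,
#' blank-line separated per sentence. Labels are taken verbatim. The
#' normalization flag is read from an explicit \code{# normalized = true/false}
#' comment when present; otherwise a graph is marked \code{normalized = TRUE}
#' when any collapsed label (\code{prep_*}, \code{prepc_*}, \code{conj_*})
#' occurs.
#'
#' @param path path to a stanford-deps text file
#' @return named list of [depgraph()] (names are sentence ids)
#' @export
read_stanford_deps <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0L]
  out <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    sent_id <- sub("^# sent_id = ", "", grep("^# sent_id = ", b, value = TRUE)[1])
    if (is.na(sent_id)) sent_id <- paste0("s", bi)
    text <- sub("^# text = ", "", grep("^# text = ", b, value = TRUE)[1])
    norm_line <- sub("^# normalized = ", "",
                     grep("^# normalized = ", b, value = TRUE)[1])
    body <- b[!startsWith(b, "#")]
    tok_lines <- body[grepl("^[0-9]+\t", body)]
    edge_lines <- setdiff(body, tok_lines)
    tf <- strsplit(tok_lines, "\t", fixed = TRUE)
    form <- vapply(tf, `[[`, "", 2)
    tokens <- data.frame(
      index = vapply(tf, function(f) as.integer(f[[1]]), 1L),
      text = form,
      lemma = tolower(vapply(tf, `[[`, "", 3)),
      pos = vapply(tf, `[[`, "", 4))
    if (all(lengths(tf) >= 6L)) {
      tokens$start <- vapply(tf, function(f) as.integer(f[[5]]), 1L)
      tokens$end <- vapply(tf, function(f) as.integer(f[[6]]), 1L)
    } else {
      sp <- token_spans(form, if (length(text)) text else NA_character_)
      tokens$start <- sp$start
      tokens$end <- sp$end
    }
    m <- regmatches(edge_lines,
                    regexec("^([A-Za-z0-9_:]+)\\(.*?-([0-9]+), .*?-([0-9]+)\\)\\s*$",
                            edge_lines))
    bad <- edge_lines[vapply(m, length, 1L) == 0L]
    if (length(bad) > 0L)
      stop("sentence ", sent_id, ": malformed edge line: ", bad[[1]])
    edges <- data.frame(
      label = vapply(m, `[[`, "", 2),
      gov = vapply(m, function(x) as.integer(x[[3]]), 1L),
      dep = vapply(m, function(x) as.integer(x[[4]]), 1L))
    oob <- setdiff(c(edges$gov, edges$dep), tokens$index)
    if (length(oob) > 0L)
      stop("sentence ", sent_id, ": token index out of range: ",
           paste(oob, collapse = ", "))
    g <- depgraph(tokens, edges,
                  normalized = if (!is.na(norm_line)) norm_line == "true"
                               else any(is_collapsed_label(edges$label)),
                  sent_id = sent_id,
                  text = if (is.na(text)) NA_character_ else text)
    out[[sent_id]] <- g
  }
  out
}

#' Write dependency graphs in stanford-deps text format
#'
#' Inverse of [read_stanford_deps()]: writing then reading yields structurally
#' equal graphs.
#'
#' @param graphs a \code{depgraph} or list of them
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
write_stanford_deps <- function(graphs, path) {
  if (inherits(graphs, "depgraph")) graphs <- list(graphs)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (g in graphs) {
    if (!is.na(g$sent_id)) writeLines(paste0("# sent_id = ", g$sent_id), con)
    if (!is.na(g$text)) writeLines(paste0("# text = ", g$text), con)
    writeLines(paste0("# normalized = ", if (isTRUE(g$normalized)) "true"
                                         else "false"), con)
    tk <- g$tokens
    writeLines(sprintf("%d\t%s\t%s\t%s\t%d\t%d", tk$index, tk$text, tk$lemma,
                       tk$pos, tk$start, tk$end), con)
    if (nrow(g$edges) > 0L) {
      word_of <- stats::setNames(tk$text, tk$index)
      writeLines(sprintf("%s(%s-%d, %s-%d)", g$edges$label,
                         word_of[as.character(g$edges$gov)], g$edges$gov,
                         word_of[as.character(g$edges$dep)], g$edges$dep), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Parse sentences through a parser adapter
#'
#' A parser adapter is any function taking one sentence string and returning a
#' [depgraph()] whose token spans align to the input text. Live parsers can be
#' plugged in by wrapping their output in this contract; the package ships
#' [fixture_parser()], a lookup backend over hand-built gold parses that fails
#' loudly on unknown input rather than returning a silently empty graph.
#'
#' @param adapter a function \code{character(1) -> depgraph}
#' @param texts character vector of sentences
#' @return list of \code{depgraph}
#' @export
parse_sentences <- function(adapter, texts) {
  stopifnot(is.function(adapter))
  lapply(texts, adapter)
}
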