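#' Extended dependency graph (EDG)
#'
#' An EDG is a sentence dependency graph after three enrichment steps:
#' multi-token entity mentions are merged into single vertices
#' ([merge_entity_tokens()]); PropBank-style numbered-argument edges
#' (\code{arg0}/\code{arg1}) are added around trigger vertices
#' ([add_numbered_args()]) so that active, passive and nominalized
#' realizations of a predicate look identical; extra-syntactic relations
#' (part-whole, is-a, member-collection, coreference) are detected
#' ([detect_extra_relations()]) and numbered arguments are propagated along
#' them to a fixpoint ([propagate_args()]).
#'
#' Fields: \code{vertices} (token columns plus \code{mention_id}),
#' \code{merged} (named list: surviving vertex index -> absorbed token
#' indices), \code{syn_edges}, \code{arg_edges} (with \code{provenance}:
#' construction-rule id or \code{propagated:<relation>}), \code{sem_edges},
#' \code{mentions}.
#'
#' @name edg
NULL

new_edg <- function(vertices, merged, syn_edges, mentions, sent_id, text) {
  structure(list(vertices = vertices, merged = merged, syn_edges = syn_edges,
                 arg_edges = empty_arg_df(), sem_edges = empty_sem_df(),
                 mentions = mentions, sent_id = sent_id, text = text),
            class = "edg")
}

#' @export
print.edg <- function(x, ...) {
  cat(sprintf("<edg%s: %d vertices, %d syn, %d arg, %d sem edges>\n",
              if (is.na(x$sent_id)) "" else paste0(" ", x$sent_id),
              nrow(x$vertices), nrow(x$syn_edges), nrow(x$arg_edges),
              nrow(x$sem_edges)))
  invisible(x)
}

entity_vertices <- function(edg) edg$vertices$index[!is.na(edg$vertices$mention_id)]

vertex_row <- function(edg, idx) edg$vertices[match(idx, edg$vertices$index), , drop = FALSE]

#' Merge entity-mention tokens into single vertices
#'
#' For each entity mention spanning several tokens, the vertex of the span's
#' syntactic head absorbs the others: edges from absorbed vertices re-attach to
#' the merged vertex, edges internal to the span are deleted, and duplicate
#' edges collapse. The merged vertex takes the mention's text and span.
#' Overlapping mentions keep the longer one (with a warning); a mention with
#' no token overlap is a validation error.
#'
#' @param graph a normalized [depgraph()]
#' @param mentions data frame with columns \code{mention_id}, \code{text},
#'   \code{start}, \code{end} (sentence-local half-open character span),
#'   \code{entity_type}
#' @return an [edg] with \code{mention_id} set on merged vertices and no arg
#'   or sem edges yet
#' @export
merge_entity_tokens <- function(graph, mentions) {
  stopifnot(inherits(graph, "depgraph"))
  if (is.null(mentions) || nrow(mentions) == 0L) mentions <- empty_mention_df()
  mentions <- as.data.frame(mentions)

  # overlapping mentions: keep the longer
  if (nrow(mentions) > 1L) {
    keep <- rep(TRUE, nrow(mentions))
    ord <- order(mentions$end - mentions$start, decreasing = TRUE)
    taken <- logical(0)
    covered <- rep(FALSE, max(mentions$end))
    for (i in ord) {
      span <- seq.int(mentions$start[i] + 1L, mentions$end[i])
      if (any(covered[span])) {
        keep[i] <- FALSE
        warning("overlapping mention '", mentions$text[i],
                "' dropped in favour of a longer mention")
      } else covered[span] <- TRUE
    }
    mentions <- mentions[keep, , drop = FALSE]
  }

  vertices <- graph$tokens
  vertices$mention_id <- NA_character_
  edges <- graph$edges
  merged <- list()

  for (i in seq_len(nrow(mentions))) {
    m <- mentions[i, ]
    span <- vertices$index[vertices$start < m$end & vertices$end > m$start]
    if (length(span) == 0L)
      stop("mention '", m$text, "' (", m$mention_id,
           ") overlaps no token in sentence")
    head_cand <- span[vapply(span, function(v) {
      gov <- edges$gov[edges$dep == v]
      length(gov) == 0L || any(!(gov %in% span))
    }, TRUE)]
    head <- if (length(head_cand) > 0L) head_cand[length(head_cand)] else span[length(span)]

    absorbed <- setdiff(span, head)
    if (length(absorbed) > 0L) {
      edges$gov[edges$gov %in% absorbed] <- head
      edges$dep[edges$dep %in% absorbed] <- head
      edges <- edges[edges$gov != edges$dep, , drop = FALSE]
      edges <- dedup_df(edges, c("label", "gov", "dep"))
      vertices <- vertices[!(vertices$index %in% absorbed), , drop = FALSE]
    }
    hi <- match(head, vertices$index)
    vertices$text[hi] <- m$text
    vertices$lemma[hi] <- tolower(m$text)
    vertices$start[hi] <- m$start
    vertices$end[hi] <- m$end
    vertices$mention_id[hi] <- m$mention_id
    merged[[as.character(head)]] <- span
  }
  rownames(vertices) <- NULL
  new_edg(vertices, merged, edges, mentions, graph$sent_id, graph$text)
}

# --- numbered-argument construction rules -----------------------------------
#
# The construction-rule inventory R1-R9 realizes the numbered-argument layer
# for verbal, passive, nominal, adjectival, relative-clause, null-argument and
# non-verbal-noun trigger realizations. When several rules fire on one vertex
# all resulting edges are kept (set union); duplicates collapse keeping the
# first provenance.

ACTIVE_POS <- c("VB", "VBZ", "VBD", "VBP", "VBG")
WH_LEMMAS <- c("which", "who", "that", "whom", "what")

syn_deps <- function(edg, v, labels = NULL, prefix = NULL) {
  e <- edg$syn_edges
  sel <- e$gov == v
  if (!is.null(labels)) sel <- sel & e$label %in% labels
  if (!is.null(prefix)) sel <- sel & startsWith(e$label, prefix)
  e$dep[sel]
}

syn_govs <- function(edg, v, labels = NULL) {
  e <- edg$syn_edges
  sel <- e$dep == v
  if (!is.null(labels)) sel <- sel & e$label %in% labels
  e$gov[sel]
}

# R7: a wh-pronoun subject under rcmod(N, t) stands for N.
wh_substitute <- function(edg, subj, trig) {
  lr <- vertex_row(edg, subj)
  if (nrow(lr) == 1L && lr$lemma %in% WH_LEMMAS) {
    n <- syn_govs(edg, trig, "rcmod")
    if (length(n) > 0L) return(n[[1]])
  }
  subj
}

#' Add numbered-argument edges around trigger vertices
#'
#' Applies the construction-rule inventory to every vertex whose lemma is a
#' lexicon trigger or a nominalization/participle of one, adding \code{arg0}
#' (agent-like) and \code{arg1} (patient-like) edges with the firing rule id
#' as provenance:
#' \itemize{
#'   \item R1 active verb: nsubj -> arg0; dobj / prep_to / prep_with -> arg1
#'   \item R2 passive participle (VBN): nsubjpass -> arg1;
#'     agent / prep_by / prep_to / prep_with -> arg0
#'   \item R3 nominalization with "between": prep_between + conj_and ->
#'     arg0/arg1
#'   \item R4 nominalization: prep_of -> arg0; prep_to / prep_with -> arg1
#'     (with a passive-nominal variant when prep_by is present:
#'     prep_by -> arg0, prep_of -> arg1)
#'   \item R5 adjectival participle on a noun with a compound dependent
#'   \item R6 reduced relative (vmod) participle
#'   \item R7 relative-clause wh-subject substitution (applied inside
#'     R1/R2's subject resolution)
#'   \item R8 null-argument gerund under prep_by/prepc_by inherits the
#'     governing verb's subject as arg0
#'   \item R9 non-verbal noun trigger (complex, dimer): nn / prep_of
#'     dependents each become arg0 (the double-arg0 shape of rule 1b)
#' }
#'
#' @param edg an [edg] with no arg edges yet
#' @param lexicon a [trigger_lexicon()]
#' @return the edg with \code{arg_edges} filled
#' @export
add_numbered_args <- function(edg, lexicon) {
  stopifnot(inherits(edg, "edg"), nrow(edg$arg_edges) == 0L)
  rows <- empty_arg_df()
  add <- function(label, pred, arg, rule) {
    for (a in arg) {
      if (length(a) == 0L || a == pred) next
      rows <<- rbind_df(rows, data.frame(label = label, pred = pred, arg = a,
                                         provenance = rule))
    }
  }
  verbal_classes <- c("ppi_verbs", "ptm_verbs", "indirect_triggers",
                      "process_triggers")
  for (vi in seq_len(nrow(edg$vertices))) {
    v <- edg$vertices$index[vi]
    pos <- edg$vertices$pos[vi]
    classes <- trigger_classes_of(edg$vertices$lemma[vi], lexicon)
    if (length(classes) == 0L) next
    is_verbal_trigger <- any(classes %in% verbal_classes)
    is_noun_trigger <- "noun_triggers" %in% classes

    if (is_verbal_trigger && pos %in% ACTIVE_POS) {                       # R1
      for (s in syn_deps(edg, v, "nsubj"))
        add("arg0", v, wh_substitute(edg, s, v), "R1")
      add("arg1", v, syn_deps(edg, v, c("dobj", "prep_to", "prep_with")), "R1")
    }
    if (is_verbal_trigger && pos == "VBN") {                              # R2
      for (s in syn_deps(edg, v, "nsubjpass"))
        add("arg1", v, wh_substitute(edg, s, v), "R2")
      add("arg0", v, syn_deps(edg, v, c("agent", "prep_by", "prep_to",
                                        "prep_with")), "R2")
    }
    if (is_verbal_trigger && startsWith(pos, "NN")) {                 # R3/R4
      btw <- syn_deps(edg, v, "prep_between")
      for (x in btw) {
        add("arg0", v, x, "R3")
        add("arg1", v, syn_deps(edg, x, "conj_and"), "R3")
      }
      by <- syn_deps(edg, v, "prep_by")
      if (length(by) > 0L) {                          # passive nominalization
        add("arg0", v, by, "R4")
        add("arg1", v, syn_deps(edg, v, "prep_of"), "R4")
      } else {
        of <- syn_deps(edg, v, "prep_of")
        add("arg0", v, of, "R4")
        add("arg1", v, syn_deps(edg, v, c("prep_to", "prep_with")), "R4")
        for (x in of) add("arg1", v, syn_deps(edg, x, "conj_and"), "R4")
      }
    }
    if (is_verbal_trigger && pos %in% c("VBG", "VBN")) {                  # R5
      heads <- syn_govs(edg, v, c("amod", "nn"))
      xs <- syn_deps(edg, v, c("nn", "dep", "dobj"))
      if (length(heads) > 0L && length(xs) > 0L) {
        add("arg1", v, xs, "R5")
        add("arg0", v, heads, "R5")
      }
    }
    if (is_verbal_trigger && pos == "VBN") {                              # R6
      for (n in syn_govs(edg, v, "vmod")) {
        add("arg1", v, n, "R6")
        add("arg0", v, syn_deps(edg, v, "prep_to"), "R6")
      }
    }
    if (is_verbal_trigger && pos == "VBG" &&                              # R8
        length(syn_deps(edg, v, "nsubj")) == 0L) {
      govs <- syn_govs(edg, v, c("prep_by", "prepc_by"))
      if (length(govs) > 0L) {
        xs <- syn_deps(edg, v, "xsubj")
        if (length(xs) == 0L) {
          for (g in govs)
            for (s in syn_deps(edg, g, "nsubj"))
              xs <- c(xs, wh_substitute(edg, s, g))
        }
        add("arg0", v, unique(xs), "R8")
      }
    }
    if (is_noun_trigger && startsWith(pos, "NN")) {                       # R9
      add("arg0", v, syn_deps(edg, v, "nn"), "R9")
      of <- syn_deps(edg, v, "prep_of")
      add("arg0", v, of, "R9")
      for (x in of) add("arg0", v, syn_deps(edg, x, "conj_and"), "R9")
    }
  }
  rows <- dedup_df(rows, c("label", "pred", "arg"))
  edg$arg_edges <- rows
  edg
}

#' Schwartz-Hearst abbreviation validity check
#'
#' Tests whether \code{short} is a plausible abbreviation of \code{long}:
#' every alphanumeric character of the short form must occur in the long form
#' in order (matched right to left), and the first character of the short form
#' must start a word of the long form.
#'
#' @param short candidate abbreviation (text inside parentheses)
#' @param long candidate definition (text before the parentheses)
#' @return logical
#' @export
is_valid_abbreviation <- function(short, long) {
  s <- tolower(short); l <- tolower(long)
  si <- nchar(s); li <- nchar(l)
  if (si == 0L || li < si) return(FALSE)
  while (si > 0L) {
    ch <- substr(s, si, si)
    if (!grepl("[a-z0-9]", ch)) {
      si <- si - 1L
      next
    }
    repeat {
      if (li <= 0L) return(FALSE)
      lc <- substr(l, li, li)
      at_word_start <- li == 1L ||
        !grepl("[a-z0-9]", substr(l, li - 1L, li - 1L))
      if (lc == ch && (si > 1L || at_word_start)) break
      li <- li - 1L
    }
    li <- li - 1L
    si <- si - 1L
  }
  TRUE
}

#' Detect extra-syntactic relations
#'
#' Adds semantic edges used by argument propagation:
#' \itemize{
#'   \item \code{part_whole} (part -> whole): a part-denoting noun (domain,
#'     region, subunit, ...; configurable in the lexicon) linked to an entity
#'     vertex via \code{prep_of}, \code{prep_in} or \code{nn};
#'   \item \code{is_a} (specific -> general): from apposition
#'     (\code{appos(general, specific)}) and from copular clauses
#'     (\code{nsubj} + \code{cop});
#'   \item \code{member_collection} (collection -> member): a plural or
#'     collection noun linked to an entity via \code{prep_including} or
#'     \code{prep_such_as};
#'   \item \code{coref}: parenthesized abbreviation/alias pairs between two
#'     entity mentions, validated Schwartz-Hearst style.
#' }
#'
#' @param edg an [edg] (numbered arguments already added)
#' @param lexicon a [trigger_lexicon()] (supplies part/collection noun lists)
#' @return the edg with \code{sem_edges} filled
#' @export
detect_extra_relations <- function(edg, lexicon = default_lexicon()) {
  stopifnot(inherits(edg, "edg"))
  rows <- empty_sem_df()
  add <- function(label, src, tgt) {
    for (t in tgt) {
      if (length(t) == 0L || t == src) next
      rows <<- rbind_df(rows, data.frame(label = label, src = src, tgt = t))
    }
  }
  ents <- entity_vertices(edg)
  for (vi in seq_len(nrow(edg$vertices))) {
    v <- edg$vertices$index[vi]
    lemma <- edg$vertices$lemma[vi]
    pos <- edg$vertices$pos[vi]
    if (lemma %in% lexicon$part_nouns) {
      tg <- syn_deps(edg, v, c("prep_of", "prep_in", "nn"))
      add("part_whole", v, intersect(tg, ents))
    }
    plural <- pos == "NNS" || sub("s$", "", lemma) %in% lexicon$collection_nouns
    if (plural) {
      tg <- syn_deps(edg, v, c("prep_including", "prep_such_as"))
      add("member_collection", v, intersect(tg, ents))
    }
  }
  ap <- edg$syn_edges[edg$syn_edges$label == "appos", , drop = FALSE]
  for (i in seq_len(nrow(ap))) add("is_a", ap$dep[i], ap$gov[i])
  cop <- edg$syn_edges[edg$syn_edges$label == "cop", , drop = FALSE]
  for (i in seq_len(nrow(cop))) {
    x <- cop$gov[i]
    for (s in syn_deps(edg, x, "nsubj")) add("is_a", s, x)
  }
  # parenthesized abbreviation / alias coreference between entity mentions
  txt <- edg$text
  if (!is.na(txt) && length(ents) > 1L) {
    vr <- edg$vertices
    for (a in ents) {
      for (b in ents) {
        if (a == b) next
        ra <- vertex_row(edg, a); rb <- vertex_row(edg, b)
        between <- substr(txt, ra$end + 1L, rb$start)
        after <- substr(txt, rb$end + 1L, rb$end + 1L)
        if (grepl("^\\s*\\($", between) && after == ")" &&
            is_valid_abbreviation(rb$text, ra$text)) {
          add("coref", a, b)
        }
      }
    }
  }
  edg$sem_edges <- dedup_df(rows, c("label", "src", "tgt"))
  edg
}

#' Propagate numbered arguments to a fixpoint
#'
#' For every \code{arg0}/\code{arg1} edge from trigger \code{t} to vertex
#' \code{n}, adds the same-label edge from \code{t} to: the whole of a
#' \code{part_whole(n, m)} relation; the member of a
#' \code{member_collection(n, m)} relation; the specific occurrence of an
#' \code{is_a(m, n)} relation (arguments flow from general to specific); both
#' directions of a \code{coref} relation; and each further conjunct of a
#' \code{conj_*(n, m)} coordination. Added edges carry provenance
#' \code{propagated:<relation>}. The operation is monotone (never removes an
#' edge), idempotent, and terminates because the edge set is bounded by
#' twice the squared vertex count.
#'
#' @param edg an [edg] with arg and sem edges present
#' @return the edg with \code{arg_edges} closed under propagation
#' @export
propagate_args <- function(edg) {
  stopifnot(inherits(edg, "edg"))
  args <- edg$arg_edges
  sem <- edg$sem_edges
  conj <- edg$syn_edges[startsWith(edg$syn_edges$label, "conj_"), , drop = FALSE]
  if (nrow(args) == 0L) return(edg)
  repeat {
    new <- empty_arg_df()
    for (i in seq_len(nrow(args))) {
      t <- args$pred[i]; n <- args$arg[i]; lab <- args$label[i]
      tgt <- c()
      prov <- c()
      pw <- sem$tgt[sem$label == "part_whole" & sem$src == n]
      mc <- sem$tgt[sem$label == "member_collection" & sem$src == n]
      ia <- sem$src[sem$label == "is_a" & sem$tgt == n]
      cr <- c(sem$tgt[sem$label == "coref" & sem$src == n],
              sem$src[sem$label == "coref" & sem$tgt == n])
      cj <- conj$dep[conj$gov == n]
      tgt <- c(pw, mc, ia, cr, cj)
      prov <- c(rep("propagated:part_whole", length(pw)),
                rep("propagated:member_collection", length(mc)),
                rep("propagated:is_a", length(ia)),
                rep("propagated:coref", length(cr)),
                rep("propagated:conj", length(cj)))
      keep <- tgt != t
      if (any(keep))
        new <- rbind_df(new, data.frame(label = lab, pred = t, arg = tgt[keep],
                                        provenance = prov[keep]))
    }
    merged <- dedup_df(rbind_df(args, new), c("label", "pred", "arg"))
    if (nrow(merged) == nrow(args)) break
    args <- merged
  }
  edg$arg_edges <- args
  edg
}

#' Build a finished EDG from a parse and entity mentions
#'
#' Convenience pipeline: normalize the parse if needed, merge entity tokens,
#' add numbered arguments, detect extra-syntactic relations, and propagate
#' arguments to a fixpoint.
#'
#' @param graph a [depgraph()]
#' @param mentions entity-mention data frame (see [merge_entity_tokens()])
#' @param lexicon a [trigger_lexicon()]
#' @return a finished [edg]
#' @export
build_edg <- function(graph, mentions, lexicon = default_lexicon()) {
  if (!graph$normalized) graph <- normalize_deps(graph)
  edg <- merge_entity_tokens(graph, mentions)
  edg <- add_numbered_args(edg, lexicon)
  edg <- detect_extra_relations(edg, lexicon)
  propagate_args(edg)
}

#' Serialize an EDG's argument and semantic edges
#'
#' Line-based debug format \code{label(pred_text-idx, arg_text-idx)
#' [provenance]}, deterministic order; intended for golden-file tests.
#'
#' @param edg an [edg]
#' @return character vector of lines
#' @export
edg_to_lines <- function(edg) {
  vr <- edg$vertices
  txt <- stats::setNames(vr$text, vr$index)
  a <- edg$arg_edges
  s <- edg$sem_edges
  lines <- c(
    if (nrow(a)) sprintf("%s(%s-%d, %s-%d) [%s]", a$label,
                         txt[as.character(a$pred)], a$pred,
                         txt[as.character(a$arg)], a$arg, a$provenance),
    if (nrow(s)) sprintf("%s(%s-%d, %s-%d)", s$label,
                         txt[as.character(s$src)], s$src,
                         txt[as.character(s$tgt)], s$tgt))
  sort(lines %||% character(0))
}

#' Export an EDG as GraphViz DOT
#'
#' Syntactic edges are drawn solid, numbered-argument edges bold, semantic
#' edges dashed; entity vertices are boxed.
#'
#' @param edg an [edg]
#' @return a single DOT document string
#' @export
edg_to_dot <- function(edg) {
  vr <- edg$vertices
  esc <- function(x) gsub('"', '\\\\"', x)
  nodes <- sprintf('  n%d [label="%s\\n%s" shape=%s];', vr$index,
                   esc(vr$text), vr$pos,
                   ifelse(is.na(vr$mention_id), "ellipse", "box"))
  e1 <- sprintf('  n%d -> n%d [label="%s"];', edg$syn_edges$gov,
                edg$syn_edges$dep, edg$syn_edges$label)
  e2 <- sprintf('  n%d -> n%d [label="%s" style=bold];', edg$arg_edges$pred,
                edg$arg_edges$arg, edg$arg_edges$label)
  e3 <- sprintf('  n%d -> n%d [label="%s" style=dashed];', edg$sem_edges$src,
                edg$sem_edges$tgt, edg$sem_edges$label)
  paste(c("digraph edg {", nodes, e1, e2, e3, "}"), collapse = "\n")
}
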