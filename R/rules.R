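#' Predicate-argument rule patterns
#'
#' Each extraction rule is a small labeled graph: vertices carry predicates
#' (entity vertex, or trigger of given lexicon classes) and edges carry
#' (label, from, to) constraints over EDG edges. The four shipped rule
#' families are:
#' \itemize{
#'   \item 1a: Protein <- arg0 <- PPI/PTM verb trigger -> arg1 -> Protein
#'   \item 1b: Protein <- arg0 <- noun trigger -> arg0 -> Protein
#'   \item 2a: Protein <- arg1 <- process trigger <- arg0 <- indirect trigger
#'     -> arg1 -> Protein
#'   \item 2b: Protein <- arg1 <- indirect trigger -> arg1 -> process trigger
#'     -> arg1 -> Protein
#' }
#'
#' @param rule_id rule identifier string
#' @param vertices named list; each element \code{list(kind = "entity")} or
#'   \code{list(kind = "trigger", classes = <lexicon set names>)}
#' @param edges data frame with columns \code{label}, \code{from}, \code{to}
#'   (names of pattern vertices)
#' @return an object of class \code{rule_pattern}
#' @export
rule_pattern <- function(rule_id, vertices, edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) stop("rule pattern must have at least one edge")
  stopifnot(all(c(edges$from, edges$to) %in% names(vertices)),
            length(vertices) <= 5L)
  # connectivity over the undirected pattern skeleton
  reach <- names(vertices)[1]
  repeat {
    nxt <- unique(c(reach, edges$to[edges$from %in% reach],
                    edges$from[edges$to %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (length(reach) != length(vertices)) stop("rule pattern must be connected")
  structure(list(rule_id = rule_id, vertices = vertices, edges = edges),
            class = "rule_pattern")
}

pattern_vertex_ok <- function(spec, edg, v, lexicon) {
  row <- vertex_row(edg, v)
  if (spec$kind == "entity") return(!is.na(row$mention_id))
  if (spec$kind == "trigger")
    return(any(trigger_classes_of(row$lemma, lexicon) %in% spec$classes))
  stop("unknown pattern vertex kind: ", spec$kind)
}

#' The four shipped predicate-argument rule patterns
#'
#' @return named list of [rule_pattern()] in precedence order (1a, 1b, 2a, 2b)
#' @export
ppi_rule_patterns <- function() {
  list(
    "1a" = rule_pattern("1a",
      vertices = list(T = list(kind = "trigger",
                               classes = c("ppi_verbs", "ptm_verbs")),
                      P1 = list(kind = "entity"), P2 = list(kind = "entity")),
      edges = data.frame(label = c("arg0", "arg1"), from = c("T", "T"),
                         to = c("P1", "P2"))),
    "1b" = rule_pattern("1b",
      vertices = list(T = list(kind = "trigger", classes = "noun_triggers"),
                      P1 = list(kind = "entity"), P2 = list(kind = "entity")),
      edges = data.frame(label = c("arg0", "arg0"), from = c("T", "T"),
                         to = c("P1", "P2"))),
    "2a" = rule_pattern("2a",
      vertices = list(I = list(kind = "trigger", classes = "indirect_triggers"),
                      PR = list(kind = "trigger", classes = "process_triggers"),
                      P1 = list(kind = "entity"), P2 = list(kind = "entity")),
      edges = data.frame(label = c("arg0", "arg1", "arg1"),
                         from = c("I", "PR", "I"), to = c("PR", "P1", "P2"))),
    "2b" = rule_pattern("2b",
      vertices = list(I = list(kind = "trigger", classes = "indirect_triggers"),
                      PR = list(kind = "trigger", classes = "process_triggers"),
                      P1 = list(kind = "entity"), P2 = list(kind = "entity")),
      edges = data.frame(label = c("arg1", "arg1", "arg1"),
                         from = c("I", "I", "PR"), to = c("P1", "PR", "P2"))))
}

#' Match a rule pattern against an EDG by backtracking subgraph search
#'
#' Returns every injective mapping of pattern vertices to EDG vertices under
#' which all vertex and edge predicates hold. When the pattern uses only
#' numbered-argument labels, only arg edges are consulted, which keeps
#' matching fast in practice despite the exponential worst case of subgraph
#' isomorphism. Results are deterministic: candidate vertices are tried in
#' ascending index order, so bindings come out in lexicographic order of the
#' bound indices.
#'
#' @param pattern a [rule_pattern()]
#' @param edg a finished [edg]
#' @param lexicon a [trigger_lexicon()]
#' @return list of named integer vectors (pattern vertex name -> EDG vertex
#'   index)
#' @export
match_pattern <- function(pattern, edg, lexicon = default_lexicon()) {
  stopifnot(inherits(pattern, "rule_pattern"), inherits(edg, "edg"))
  pv <- names(pattern$vertices)
  labs <- unique(pattern$edges$label)
  edge_df <- if (all(labs %in% c("arg0", "arg1"))) {
    data.frame(label = edg$arg_edges$label, gov = edg$arg_edges$pred,
               dep = edg$arg_edges$arg)
  } else {
    rbind_df(
      data.frame(label = edg$arg_edges$label, gov = edg$arg_edges$pred,
                 dep = edg$arg_edges$arg),
      edg$syn_edges[, c("label", "gov", "dep")],
      data.frame(label = edg$sem_edges$label, gov = edg$sem_edges$src,
                 dep = edg$sem_edges$tgt))
  }
  have <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edge_df)))
    assign(paste(edge_df$label[i], edge_df$gov[i], edge_df$dep[i]), TRUE,
           envir = have)
  edge_ok <- function(label, g, d)
    exists(paste(label, g, d), envir = have, inherits = FALSE)

  cands <- lapply(pattern$vertices, function(spec) {
    v <- edg$vertices$index
    sort(v[vapply(v, function(x) pattern_vertex_ok(spec, edg, x, lexicon), TRUE)])
  })
  results <- list()
  assign_next <- function(k, bound) {
    if (k > length(pv)) {
      results[[length(results) + 1L]] <<- bound
      return(invisible())
    }
    name <- pv[[k]]
    for (v in cands[[k]]) {
      if (v %in% bound) next
      bound2 <- c(bound, stats::setNames(v, name))
      ok <- TRUE
      for (i in seq_len(nrow(pattern$edges))) {
        f <- pattern$edges$from[i]; t <- pattern$edges$to[i]
        if (f %in% names(bound2) && t %in% names(bound2) &&
            !edge_ok(pattern$edges$label[i], bound2[[f]], bound2[[t]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) assign_next(k + 1L, bound2)
    }
  }
  assign_next(1L, stats::setNames(integer(0), character(0)))
  results
}

# Coreference groups among entity vertices: union-find over coref edges and
# is_a edges connecting two entity mentions (an apposition between two named
# entities is coreference in practice). Returns a named integer vector mapping
# vertex index -> group representative vertex (textually first mention).
coref_groups <- function(edg) {
  ents <- entity_vertices(edg)
  parent <- stats::setNames(ents, ents)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[as.character(max(ra, rb))]] <<- min(ra, rb)
  }
  s <- edg$sem_edges
  link <- s[(s$label == "coref" | s$label == "is_a") &
              s$src %in% ents & s$tgt %in% ents, , drop = FALSE]
  for (i in seq_len(nrow(link))) union_(link$src[i], link$tgt[i])
  reps <- vapply(ents, find, 1L)
  # representative = textually first mention of the group
  starts <- stats::setNames(edg$vertices$start, edg$vertices$index)
  out <- reps
  for (r in unique(reps)) {
    members <- ents[reps == r]
    out[reps == r] <- members[which.min(starts[as.character(members)])]
  }
  stats::setNames(out, ents)
}

#' Extract PPI pairs from a finished EDG
#'
#' Applies the four rule patterns in precedence order. Bindings whose protein
#' slots map to entity vertices become candidate pairs; self-pairs (same
#' mention, same normalized surface form, or coreferent aliases of one
#' another) are removed; pairs are collapsed to coreference-group
#' representatives (the textually first mention of each group) and
#' deduplicated keeping the lowest-numbered rule id.
#'
#' @param edg a finished [edg]
#' @param lexicon a [trigger_lexicon()]
#' @return a PPI-pair data frame (doc_id, sentence_index, mention_a,
#'   mention_b, name_a, name_b, trigger, rule_id); sentence/document fields
#'   are \code{NA} at this level and filled in by [extract_document()]
#' @export
extract_pairs <- function(edg, lexicon = default_lexicon()) {
  stopifnot(inherits(edg, "edg"))
  groups <- coref_groups(edg)
  vr <- edg$vertices
  out <- empty_pair_df()
  for (pat in ppi_rule_patterns()) {
    slots <- names(pat$vertices)[vapply(pat$vertices,
                                        function(s) s$kind == "entity", TRUE)]
    trig_slot <- names(pat$vertices)[vapply(pat$vertices, function(s)
      s$kind == "trigger", TRUE)][1]
    for (b in match_pattern(pat, edg, lexicon)) {
      va <- groups[[as.character(b[[slots[1]]])]]
      vb <- groups[[as.character(b[[slots[2]]])]]
      ra <- vertex_row(edg, va); rb <- vertex_row(edg, vb)
      if (va == vb) next
      if (normalize_name(ra$text) == normalize_name(rb$text)) next
      if (ra$start > rb$start) {
        tmp <- ra; ra <- rb; rb <- tmp
      }
      trig <- vertex_row(edg, b[[trig_slot]])$lemma
      tb <- trigger_base(trig, lexicon)
      out <- rbind_df(out, data.frame(
        doc_id = NA_character_, sentence_index = NA_integer_,
        mention_a = ra$mention_id, mention_b = rb$mention_id,
        name_a = ra$text, name_b = rb$text,
        trigger = if (is.na(tb)) trig else tb,
        rule_id = pat$rule_id))
    }
  }
  if (nrow(out) == 0L) return(out)
  key <- pair_key(out$mention_a, out$mention_b)
  out <- out[!duplicated(key), , drop = FALSE]  # patterns applied in rule order
  rownames(out) <- NULL
  out
}

#' Extract PPI pairs from a whole document
#'
#' Runs [build_edg()] + [extract_pairs()] over every sentence of a BioC
#' document. \code{parses} is a list of [depgraph()] indexed by document-wide
#' sentence ordinal; sentences lacking a parse are skipped with a warning.
#'
#' @param doc a \code{bioc_document} (see [read_collection()])
#' @param parses list of \code{depgraph}, indexed by sentence index; entries
#'   may be \code{NULL} for unparsed sentences
#' @param lexicon a [trigger_lexicon()]
#' @return PPI-pair data frame with \code{doc_id} and \code{sentence_index}
#'   filled
#' @export
extract_document <- function(doc, parses, lexicon = default_lexicon()) {
  stopifnot(inherits(doc, "bioc_document"))
  out <- empty_pair_df()
  sents <- document_sentences(doc)
  for (i in seq_len(nrow(sents))) {
    g <- if (i <= length(parses)) parses[[i]] else NULL
    if (is.null(g)) {
      warning("document ", doc$doc_id, ": no parse for sentence ", i,
              "; skipped")
      next
    }
    men <- sentence_mentions(doc, i)
    edg <- build_edg(g, men, lexicon)
    pairs <- extract_pairs(edg, lexicon)
    if (nrow(pairs) > 0L) {
      pairs$doc_id <- doc$doc_id
      pairs$sentence_index <- i
      out <- rbind_df(out, pairs)
    }
  }
  out
}

#' Write extracted pairs as TSV
#'
#' @param pairs PPI-pair data frame
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
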