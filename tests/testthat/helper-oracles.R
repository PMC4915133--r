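# Shared helpers and independent oracles for the property suites.

# --- canonical pair-set representation --------------------------------------

pair_set <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  a <- normalize_name(pairs$name_a)
  b <- normalize_name(pairs$name_b)
  sort(unique(paste(pmin(a, b), pmax(a, b))))
}

expected_set <- function(expected_pairs) {
  sort(vapply(expected_pairs, function(p) {
    n <- sort(normalize_name(p))
    paste(n, collapse = " ")
  }, ""))
}

run_fixture_pairs <- function(case, lexicon = default_lexicon()) {
  edg <- build_edg(case$graph, case$mentions, lexicon)
  extract_pairs(edg, lexicon)
}

# --- random graph generators ------------------------------------------------

# A random finished-EDG-shaped object (class edg) with arbitrary arg, syn and
# sem edges over n vertices; some vertices are entity mentions, some carry
# trigger lemmas. Used to exercise the matcher and propagation directly.
random_edg <- function(n = 6L, p_edge = 0.25) {
  lemmas <- sample(c("bind", "activate", "block", "mediate", "activity",
                     "interaction", "complex", "dimer", "protein", "domain",
                     "cell", "xyz"), n, replace = TRUE)
  is_ent <- stats::runif(n) < 0.4
  vertices <- data.frame(
    index = seq_len(n),
    text = ifelse(is_ent, paste0("P", seq_len(n)), lemmas),
    lemma = ifelse(is_ent, paste0("p", seq_len(n)), lemmas),
    pos = sample(c("NN", "NNP", "VBZ", "VBN", "VBG"), n, replace = TRUE),
    start = (seq_len(n) - 1L) * 6L, end = (seq_len(n) - 1L) * 6L + 4L,
    mention_id = ifelse(is_ent, paste0("m", seq_len(n)), NA_character_))
  rand_edges <- function(labels) {
    out <- data.frame(label = character(), gov = integer(), dep = integer())
    for (g in seq_len(n)) for (d in seq_len(n)) {
      if (g != d && stats::runif(1) < p_edge / length(labels))
        for (lab in labels) if (stats::runif(1) < 0.6)
          out <- rbind(out, data.frame(label = lab, gov = g, dep = d))
    }
    unique(out)
  }
  arg <- rand_edges(c("arg0", "arg1"))
  arg <- data.frame(label = arg$label, pred = arg$gov, arg = arg$dep,
                    provenance = rep("R1", nrow(arg)))
  syn <- rand_edges(c("nsubj", "dobj", "conj_and", "prep_of"))
  semr <- rand_edges(c("part_whole", "is_a", "member_collection", "coref"))
  sem <- data.frame(label = semr$label, src = semr$gov, tgt = semr$dep)
  structure(list(vertices = vertices, merged = list(), syn_edges = syn,
                 arg_edges = arg, sem_edges = sem,
                 mentions = vertices[is_ent, c("text", "start", "end")],
                 sent_id = NA_character_, text = NA_character_),
            class = "edg")
}

# A random basic (uncollapsed) dependency tree over n tokens with prep/pobj
# chains and conj edges, for normalize_deps properties.
random_basic_depgraph <- function(n = 8L) {
  words <- sample(c("alpha", "beta", "gamma", "of", "with", "binds", "and",
                    "delta", "protein", "to"), n, replace = TRUE)
  tokens <- data.frame(index = seq_len(n), text = words, lemma = words,
                       pos = sample(c("NN", "VBZ", "IN"), n, replace = TRUE),
                       start = (seq_len(n) - 1L) * 8L,
                       end = (seq_len(n) - 1L) * 8L + nchar(words))
  lab <- character(0); gov <- integer(0); dep <- integer(0)
  for (i in 2:n) {
    g <- sample(seq_len(i - 1L), 1L)
    l <- sample(c("nsubj", "dobj", "prep", "pobj", "conj_and", "det", "amod"),
                1L)
    lab <- c(lab, l); gov <- c(gov, g); dep <- c(dep, i)
  }
  depgraph(tokens, data.frame(label = lab, gov = gov, dep = dep),
           normalized = FALSE)
}

# --- brute-force pattern-matching oracle ------------------------------------

# Enumerates every injective assignment of pattern vertices to EDG vertices
# and filters by the vertex and edge predicates, using the same edge universe
# contract as match_pattern (arg-only patterns consult only arg edges).
brute_force_match <- function(pattern, edg, lexicon = default_lexicon()) {
  pv <- names(pattern$vertices)
  labs <- unique(pattern$edges$label)
  universe <- if (all(labs %in% c("arg0", "arg1"))) {
    data.frame(label = edg$arg_edges$label, gov = edg$arg_edges$pred,
               dep = edg$arg_edges$arg)
  } else {
    rbind(
      data.frame(label = edg$arg_edges$label, gov = edg$arg_edges$pred,
                 dep = edg$arg_edges$arg),
      edg$syn_edges[, c("label", "gov", "dep")],
      data.frame(label = edg$sem_edges$label, gov = edg$sem_edges$src,
                 dep = edg$sem_edges$tgt))
  }
  ekeys <- paste(universe$label, universe$gov, universe$dep)
  vs <- edg$vertices$index
  # vertex eligibility per pattern slot, precomputed (assignments using an
  # ineligible vertex cannot match by definition)
  elig <- lapply(pattern$vertices, function(spec)
    vs[vapply(vs, function(x)
      edgppi:::pattern_vertex_ok(spec, edg, x, lexicon), TRUE)])
  results <- list()
  enumerate <- function(k, assign) {
    if (k > length(pv)) {
      for (i in seq_len(nrow(pattern$edges))) {
        key <- paste(pattern$edges$label[i], assign[[pattern$edges$from[i]]],
                     assign[[pattern$edges$to[i]]])
        if (!(key %in% ekeys)) return(invisible())
      }
      results[[length(results) + 1L]] <<- assign
      return(invisible())
    }
    for (v in elig[[k]]) {
      if (v %in% assign) next
      a2 <- c(assign, stats::setNames(v, pv[[k]]))
      enumerate(k + 1L, a2)
    }
  }
  enumerate(1L, stats::setNames(integer(0), character(0)))
  results
}

canonical_bindings <- function(bindings) {
  sort(vapply(bindings, function(b)
    paste(names(b), b, collapse = ";"), ""))
}

# --- igraph reachability oracle for argument propagation --------------------

# The propagated argument set of (t, n) is {n} plus every vertex reachable
# from n over the propagation relation: part_whole/member_collection src->tgt,
# is_a tgt->src, coref both ways, conj_* gov->dep. The trigger t itself never
# becomes an argument, and since the arg edge (t, t) is never created,
# propagation cannot route through t either — so reachability is computed on
# the relation graph with vertex t deleted.
propagation_oracle <- function(edg) {
  sem <- edg$sem_edges
  conj <- edg$syn_edges[startsWith(edg$syn_edges$label, "conj_"), ,
                        drop = FALSE]
  from <- c(sem$src[sem$label %in% c("part_whole", "member_collection")],
            sem$tgt[sem$label == "is_a"],
            sem$src[sem$label == "coref"], sem$tgt[sem$label == "coref"],
            conj$gov)
  to <- c(sem$tgt[sem$label %in% c("part_whole", "member_collection")],
          sem$src[sem$label == "is_a"],
          sem$tgt[sem$label == "coref"], sem$src[sem$label == "coref"],
          conj$dep)
  n_v <- max(edg$vertices$index)
  g <- igraph::make_empty_graph(n = n_v, directed = TRUE)
  igraph::V(g)$name <- as.character(seq_len(n_v))
  if (length(from) > 0L) g <- igraph::add_edges(g, as.character(rbind(from, to)))
  out <- data.frame(label = character(), pred = integer(), arg = integer())
  a <- edg$arg_edges
  for (i in seq_len(nrow(a))) {
    gm <- igraph::delete_vertices(g, as.character(a$pred[i]))
    comp <- igraph::subcomponent(gm, as.character(a$arg[i]), mode = "out")
    reach <- as.integer(igraph::as_ids(comp))
    reach <- setdiff(unique(c(a$arg[i], reach)), a$pred[i])
    out <- rbind(out, data.frame(label = a$label[i], pred = a$pred[i],
                                 arg = reach))
  }
  unique(out)
}

arg_edge_set <- function(edg) {
  sort(paste(edg$arg_edges$label, edg$arg_edges$pred, edg$arg_edges$arg))
}

edge_set <- function(graph) {
  sort(paste(graph$edges$label, graph$edges$gov, graph$edges$dep))
}
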