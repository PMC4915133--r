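lex <- default_lexicon()

fx_edg <- function(case_id, lexicon = lex) {
  case <- load_fixture(case_id)
  build_edg(case$graph, case$mentions, lexicon)
}

test_that("merge_entity_tokens absorbs multi-token mentions into the head", {
  case <- load_fixture("table1_row01")  # "transferrin receptor" = tokens 5-6
  e <- merge_entity_tokens(case$graph, case$mentions)
  expect_s3_class(e, "edg")
  expect_equal(sort(edgppi:::entity_vertices(e)), c(1L, 6L))
  v6 <- edgppi:::vertex_row(e, 6L)
  expect_equal(v6$text, "transferrin receptor")
  expect_false(5L %in% e$vertices$index)          # absorbed
  expect_equal(e$merged[["6"]], c(5L, 6L))
  # internal nn(6,5) edge is gone, external prep_to(2,6) survives
  expect_false(any(e$syn_edges$dep == 5L | e$syn_edges$gov == 5L))
  expect_true(any(e$syn_edges$label == "prep_to" & e$syn_edges$dep == 6L))
})

test_that("seven-token mention merges to its syntactic head", {
  case <- load_fixture("table1_row02")
  e <- merge_entity_tokens(case$graph, case$mentions)
  # head of "Plasminogen activator inhibitor 1 (PAI)" is "inhibitor" (tok 3)
  expect_true(3L %in% edgppi:::entity_vertices(e))
  expect_equal(length(e$merged[["3"]]), 7L)
  expect_equal(edgppi:::vertex_row(e, 3L)$text,
               "Plasminogen activator inhibitor 1 (PAI)")
  expect_true(any(e$syn_edges$label == "nsubjpass" & e$syn_edges$dep == 3L))
})

test_that("overlapping mentions keep the longer; disjoint mention errors", {
  case <- load_fixture("table1_row01")
  men <- rbind(case$mentions,
               data.frame(mention_id = "mx", text = "receptor", start = 16L,
                          end = 24L, entity_type = "protein"))
  expect_warning(e <- merge_entity_tokens(case$graph, men), "overlapping")
  expect_length(edgppi:::entity_vertices(e), 2L)

  men2 <- data.frame(mention_id = "my", text = "ghost", start = 200L,
                     end = 205L, entity_type = "protein")
  expect_error(merge_entity_tokens(case$graph, men2), "overlaps no token")
})

test_that("R1/R2/R4 make active, passive and nominal forms identical", {
  forms <- lapply(c("fig1_active", "fig1_passive", "fig1_nominal"), fx_edg)
  pair_sets <- lapply(forms, function(e) pair_set(extract_pairs(e, lex)))
  expect_equal(pair_sets[[1]], pair_sets[[2]])
  expect_equal(pair_sets[[2]], pair_sets[[3]])
  # and the rule provenance differs as documented
  provs <- lapply(forms, function(e) unique(e$arg_edges$provenance))
  expect_true("R1" %in% provs[[1]])
  expect_true("R2" %in% provs[[2]])
  expect_true("R4" %in% provs[[3]])
})

test_that("R4 passive-nominal variant maps prep_by to arg0, prep_of to arg1", {
  e <- fx_edg("fig1_nominal")  # "Activation of STAT1 by JAK2"
  a <- e$arg_edges
  expect_true(any(a$label == "arg0" & a$arg == 5L))  # JAK2
  expect_true(any(a$label == "arg1" & a$arg == 3L))  # STAT1
})

test_that("R5 adjectival participle fires only with head noun and dependent", {
  e <- fx_edg("table1_row04")  # "Raf-1-binding proteins, Ras"
  a <- e$arg_edges
  expect_true(any(a$label == "arg1" & a$pred == 2L & a$arg == 1L &
                    a$provenance == "R5"))
  expect_true(any(a$label == "arg0" & a$pred == 2L & a$arg == 3L &
                    a$provenance == "R5"))
  # "activated MAPK" in row06 has no compound dependent -> R5 must not fire
  e6 <- fx_edg("table1_row06")
  expect_false(any(e6$arg_edges$pred == 14L))
})

test_that("R6 reduced relative attaches the modified noun as arg1", {
  e <- fx_edg("table1_row06")  # "Structure of ERK2 bound to PEA-15 ..."
  a <- e$arg_edges
  expect_true(any(a$label == "arg1" & a$pred == 4L & a$arg == 3L &
                    a$provenance == "R6"))
  expect_true(any(a$label == "arg0" & a$pred == 4L & a$arg == 6L))
})

test_that("R7 substitutes the relativized noun for the wh-subject", {
  e <- fx_edg("table1_row05")  # "Shc, which specifically binds ..."
  a <- e$arg_edges
  expect_true(any(a$label == "arg0" & a$pred == 5L & a$arg == 1L))
  expect_false(any(a$arg == 3L))  # "which" never becomes an argument
})

test_that("R8 null-argument gerund inherits the governing verb's subject", {
  e <- fx_edg("table1_row08")
  a <- e$arg_edges
  expect_true(any(a$label == "arg0" & a$pred == 8L & a$arg == 2L &
                    a$provenance == "R8"))
})

test_that("R9 noun triggers produce double arg0 edges", {
  # synthetic: "the JAK2/STAT1 complex" as nn(complex, JAK2), nn(complex, STAT1)
  tk <- data.frame(index = 1:3, text = c("JAK2", "STAT1", "complex"),
                   lemma = c("jak2", "stat1", "complex"),
                   pos = c("NNP", "NNP", "NN"),
                   start = c(0L, 5L, 11L), end = c(4L, 10L, 18L))
  g <- depgraph(tk, data.frame(label = c("nn", "nn"), gov = c(3L, 3L),
                               dep = c(1L, 2L)), normalized = TRUE,
                text = "JAK2 STAT1 complex")
  men <- data.frame(mention_id = c("m1", "m2"), text = c("JAK2", "STAT1"),
                    start = c(0L, 5L), end = c(4L, 10L),
                    entity_type = "protein")
  e <- build_edg(g, men, lex)
  a <- e$arg_edges
  expect_equal(sum(a$label == "arg0" & a$pred == 3L & a$provenance == "R9"), 2L)
  p <- extract_pairs(e, lex)
  expect_equal(p$rule_id, "1b")
  expect_equal(pair_set(p), "jak2 stat1")
})

test_that("is_valid_abbreviation implements the right-to-left character check", {
  expect_true(is_valid_abbreviation("PAI", "Plasminogen activator inhibitor"))
  expect_true(is_valid_abbreviation("HVEM", "herpes virus entry mediator"))
  expect_false(is_valid_abbreviation("XYZ", "Plasminogen activator inhibitor"))
  # first character must start a word
  expect_false(is_valid_abbreviation("RT", "parthenogenesis t"))
  expect_false(is_valid_abbreviation("", "anything"))
  expect_false(is_valid_abbreviation("toolong", "tl"))
})

test_that("extra-syntactic relations are detected per their licensing contexts", {
  e5 <- fx_edg("table1_row05")   # SH2 domain of GRB2 -> part_whole
  expect_true(any(e5$sem_edges$label == "part_whole" & e5$sem_edges$src == 8L &
                    e5$sem_edges$tgt == 10L))
  e11 <- fx_edg("table1_row11")  # proteins, including RAD9 -> member_collection
  expect_true(any(e11$sem_edges$label == "member_collection" &
                    e11$sem_edges$tgt == 12L))
  e9 <- fx_edg("table1_row09")   # copular is_a(CD5, antigen)
  expect_true(any(e9$sem_edges$label == "is_a" & e9$sem_edges$src == 1L &
                    e9$sem_edges$tgt == 5L))
  e10 <- fx_edg("table1_row10")  # appositive is_a(specific, general)
  expect_true(any(e10$sem_edges$label == "is_a" & e10$sem_edges$src == 11L &
                    e10$sem_edges$tgt == 6L))
  e2 <- fx_edg("table1_row02")   # "(PAI)" inside the mention: no self-coref
  expect_false(any(e2$sem_edges$label == "coref"))
})

test_that("parenthesized abbreviation coref links entity mentions", {
  tk <- data.frame(index = 1:4,
                   text = c("Interleukin-2", "(", "IL-2", ")"),
                   lemma = c("interleukin-2", "(", "il-2", ")"),
                   pos = c("NNP", "-LRB-", "NNP", "-RRB-"),
                   start = c(0L, 14L, 15L, 19L), end = c(13L, 15L, 19L, 20L))
  g <- depgraph(tk, data.frame(label = c("appos", "punct", "punct"),
                               gov = c(1L, 3L, 3L), dep = c(3L, 2L, 4L)),
                normalized = TRUE, text = "Interleukin-2 (IL-2)")
  men <- data.frame(mention_id = c("m1", "m2"),
                    text = c("Interleukin-2", "IL-2"),
                    start = c(0L, 15L), end = c(13L, 19L),
                    entity_type = "protein")
  e <- build_edg(g, men, lex)
  expect_true(any(e$sem_edges$label == "coref" & e$sem_edges$src == 1L &
                    e$sem_edges$tgt == 3L))
})

test_that("propagate_args matches the igraph reachability oracle (property)", {
  set.seed(7)
  for (i in 1:60) {
    e <- random_edg(sample(3:7, 1))
    p <- propagate_args(e)
    expect_setequal(arg_edge_set(p),
                    with(propagation_oracle(e), paste(label, pred, arg)))
  }
})

test_that("propagate_args is idempotent and monotone (property)", {
  set.seed(8)
  for (i in 1:60) {
    e <- random_edg(sample(3:7, 1))
    p1 <- propagate_args(e)
    p2 <- propagate_args(p1)
    expect_identical(arg_edge_set(p2), arg_edge_set(p1))       # idempotent
    expect_true(all(arg_edge_set(e) %in% arg_edge_set(p1)))    # monotone
  }
})

test_that("propagated edges carry provenance and never point at the trigger", {
  e <- fx_edg("table1_row13")
  a <- e$arg_edges
  expect_true(all(a$pred != a$arg))
  prop <- a[startsWith(a$provenance, "propagated:"), ]
  expect_true(nrow(prop) > 0)
  expect_true(all(prop$provenance %in% paste0("propagated:",
    c("part_whole", "member_collection", "is_a", "coref", "conj"))))
})

test_that("edg_to_lines and edg_to_dot serialize deterministically", {
  e <- fx_edg("fig1_active")
  lines <- edg_to_lines(e)
  expect_equal(lines, sort(lines))
  expect_true(any(grepl("^arg0\\(activates-2, JAK2-1\\) \\[R1\\]$", lines)))
  dot <- edg_to_dot(e)
  expect_match(dot, "digraph edg", fixed = TRUE)
  expect_match(dot, "shape=box")         # entity vertices boxed
  expect_match(dot, "style=bold")        # arg edges bold
})
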