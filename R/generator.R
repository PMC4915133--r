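# ---------------------------------------------------------------------------
# Synthetic fixture generator: builds sentence cases from construct templates
# with substituted protein names and trigger verbs, deriving the expected
# pair set from the template's slot semantics. Deterministic given
# (construct, trigger, names, seed).

#' Construct templates known to the synthetic fixture generator
#'
#' @seealso [generate_fixture()]
#' @export
GENERATOR_CONSTRUCTS <- c(
  "active", "passive", "nominalization", "adjective", "full_relative",
  "reduced_relative", "coordination", "null_argument", "is_a", "appositive",
  "member_collection", "part_whole", "combination")

#' Protein-like names the generator samples from when none are supplied
#'
#' @seealso [generate_fixture()]
#' @export
GENERATOR_NAME_POOL <- c(
  "TRAF2", "RAD51", "SMAD4", "CDC42", "BRCA1", "MDM2", "ATM", "CHK2",
  "EGFR", "GRB2", "SOS1", "RAS", "RAF1", "MEK1", "ERK2", "AKT1", "PTEN",
  "TP53", "XRCC4", "KU70")

#' Simple English verb morphology for trigger lemmas
#'
#' \code{verb_3sg} appends "s"; \code{verb_vbn} knows the irregular
#' bind/bound and otherwise appends -(e)d; \code{verb_vbg} drops a final
#' silent "e" before -ing; \code{verb_nominal} applies the -ion
#' nominalization rule (\code{-te -> -tion}, \code{-t -> -tion}) and falls
#' back to the gerund (binding, crosslinking).
#'
#' @param lemma verb lemma, lowercase
#' @return inflected form, lowercase
#' @export
verb_3sg <- function(lemma) paste0(lemma, "s")

#' @rdname verb_3sg
#' @export
verb_vbn <- function(lemma) {
  if (lemma == "bind") return("bound")
  if (grepl("e$", lemma)) paste0(lemma, "d") else paste0(lemma, "ed")
}

#' @rdname verb_3sg
#' @export
verb_vbg <- function(lemma) paste0(sub("e$", "", lemma), "ing")

#' @rdname verb_3sg
#' @export
verb_nominal <- function(lemma) {
  if (grepl("te$", lemma)) return(sub("e$", "ion", lemma))
  if (grepl("t$", lemma)) return(paste0(lemma, "ion"))
  verb_vbg(lemma)
}

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate a synthetic fixture case
#'
#' Instantiates one of the 13 construct templates with a trigger verb and
#' protein names, returning the same structure as a [load_fixture()] sentence
#' case: gold parse, mentions, and the expected pair set derived from the
#' template's argument-slot semantics (not from running the extractor).
#'
#' @param construct one of [GENERATOR_CONSTRUCTS]
#' @param trigger verb lemma; must be a PPI or PTM verb of \code{lexicon}
#'   (noun triggers are rejected: these templates inflect the verb)
#' @param names character vector of protein names (2, or 3 for
#'   \code{coordination}/\code{combination}); drawn from
#'   [GENERATOR_NAME_POOL] under \code{seed} when omitted
#' @param seed integer seed used only when \code{names} is omitted
#' @param lexicon a [trigger_lexicon()]
#' @return fixture case list (see [load_fixture()])
#' @export
generate_fixture <- function(construct, trigger = "bind", names = NULL,
                             seed = 0L, lexicon = default_lexicon()) {
  construct <- match.arg(construct, GENERATOR_CONSTRUCTS)
  if (!trigger %in% c(lexicon$ppi_verbs, lexicon$ptm_verbs))
    stop("trigger '", trigger, "' is not a PPI/PTM verb in the lexicon; ",
         "the generator templates require a verbal trigger")
  n_names <- if (construct %in% c("coordination", "combination")) 3L else 2L
  if (is.null(names)) {
    set.seed(seed)
    names <- sample(GENERATOR_NAME_POOL, n_names)
  }
  if (length(names) != n_names)
    stop("construct '", construct, "' needs ", n_names, " names")
  if (anyDuplicated(normalize_name(names)))
    stop("protein names must be distinct")

  p1 <- names[[1]]; p2 <- names[[2]]
  p3 <- if (n_names == 3L) names[[3]] else NULL
  v3 <- verb_3sg(trigger); vn <- verb_vbn(trigger)
  vg <- verb_vbg(trigger); nom <- verb_nominal(trigger)
  np <- function(x) paste0(x, "|NNP")
  vt <- function(form, pos) paste0(form, "|", pos, "|", trigger)

  tpl <- switch(construct,
    active = list(
      tokens = paste(np(p1), vt(v3, "VBZ"), np(p2)),
      edges = "nsubj(2,1) dobj(2,3)",
      mentions = list(tk(1, 1), tk(3, 3)),
      expected = list(c(p1, p2))),
    passive = list(
      tokens = paste(np(p2), "is|VBZ|be", vt(vn, "VBN"), "by|IN", np(p1)),
      edges = "nsubjpass(3,1) auxpass(3,2) prep_by(3,5)",
      mentions = list(tk(1, 1), tk(5, 5)),
      expected = list(c(p1, p2))),
    nominalization = list(
      tokens = paste(paste0(cap1(nom), "|NN|", nom), "of|IN", np(p1),
                     "by|IN", np(p2)),
      edges = "prep_of(1,3) prep_by(1,5)",
      mentions = list(tk(3, 3), tk(5, 5)),
      expected = list(c(p1, p2))),
    adjective = list(
      tokens = paste(paste0(p1, "-|NNP|", tolower(p1)),
                     paste0("~", vt(vg, "VBG")),
                     "proteins|NNS|protein ~,|,", np(p2)),
      edges = "amod(3,2) nn(2,1) appos(3,5) punct(3,4)",
      mentions = list(list(text = p1), tk(5, 5)),
      expected = list(c(p1, p2))),
    full_relative = list(
      tokens = paste(np(p1), "~,|, which|WDT specifically|RB",
                     vt(v3, "VBZ"), np(p2)),
      edges = "rcmod(1,5) punct(1,2) nsubj(5,3) advmod(5,4) dobj(5,6)",
      mentions = list(tk(1, 1), tk(6, 6)),
      expected = list(c(p1, p2))),
    reduced_relative = list(
      tokens = paste("Structure|NN of|IN", np(p1), vt(vn, "VBN"), "to|TO",
                     np(p2), "reveals|VBZ|reveal a|DT mechanism|NN"),
      edges = paste("nsubj(7,1) prep_of(1,3) vmod(3,4) prep_to(4,6)",
                    "dobj(7,9) det(9,8)"),
      mentions = list(tk(3, 3), tk(6, 6)),
      expected = list(c(p1, p2))),
    coordination = list(
      tokens = paste(np(p1), vt(v3, "VBZ"), np(p2), "and|CC", np(p3)),
      edges = "nsubj(2,1) dobj(2,3) cc(3,4) conj_and(3,5) dobj(2,5)",
      mentions = list(tk(1, 1), tk(3, 3), tk(5, 5)),
      expected = list(c(p1, p2), c(p1, p3))),
    null_argument = list(
      tokens = paste(np(p1), "can|MD repress|VB transcription|NN by|IN",
                     vt(vg, "VBG"), "to|TO", np(p2)),
      edges = "nsubj(3,1) aux(3,2) dobj(3,4) prepc_by(3,6) prep_to(6,8)",
      mentions = list(tk(1, 1), tk(8, 8)),
      expected = list(c(p1, p2))),
    is_a = list(
      tokens = paste(np(p1), "is|VBZ|be a|DT protein|NN which|WDT",
                     vt(v3, "VBZ"), "to|TO", np(p2)),
      edges = "nsubj(4,1) cop(4,2) det(4,3) rcmod(4,6) nsubj(6,5) prep_to(6,8)",
      mentions = list(tk(1, 1), tk(8, 8)),
      expected = list(c(p1, p2))),
    appositive = list(
      tokens = paste(np(p1), vt(v3, "VBZ"), "its|PRP$ receptor|NN ~,|,",
                     np(p2)),
      edges = "nsubj(2,1) dobj(2,4) poss(4,3) punct(4,5) appos(4,6)",
      mentions = list(tk(1, 1), tk(6, 6)),
      expected = list(c(p1, p2))),
    member_collection = list(
      tokens = paste(np(p1), vt(v3, "VBZ"),
                     "several|JJ proteins|NNS|protein ~,|,",
                     "including|VBG|include", np(p2)),
      edges = "nsubj(2,1) dobj(2,4) amod(4,3) punct(4,5) prep_including(4,7)",
      mentions = list(tk(1, 1), tk(7, 7)),
      expected = list(c(p1, p2))),
    part_whole = list(
      tokens = paste(np(p1), vt(v3, "VBZ"),
                     "to|TO a|DT distinct|JJ domain|NN in|IN", np(p2)),
      edges = "nsubj(2,1) prep_to(2,6) det(6,4) amod(6,5) prep_in(6,8)",
      mentions = list(tk(1, 1), tk(8, 8)),
      expected = list(c(p1, p2))),
    combination = list(
      tokens = paste(np(p1), vt(v3, "VBZ"), "two|CD ligands|NNS|ligand ~,|,",
                     np(p2), "and|CC", np(p3)),
      edges = paste("nsubj(2,1) dobj(2,4) num(4,3) punct(4,5) appos(4,6)",
                    "cc(6,7) conj_and(6,8)"),
      mentions = list(tk(1, 1), tk(6, 6), tk(8, 8)),
      expected = list(c(p1, p2), c(p1, p3))))

  case_id <- paste0("gen_", construct, "_", trigger, "_",
                    paste(tolower(names), collapse = "_"))
  out <- fx_case(case_id, tpl$tokens, tpl$edges, tpl$mentions, tpl$expected,
                 construct)
  out$trigger <- trigger
  out$names <- names
  out
}
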