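`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; reported percentages in the
#' evaluation tables use conventional half-up rounding (83.45 -> 83.5).
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Normalize a protein name for matching
#'
#' Lowercases and strips hyphens, slashes and whitespace so that surface
#' variants ("Raf-1", "raf 1") compare equal. Used for gold-pair scoring and
#' the document-wide known-pair index.
#'
#' @param x character vector of names
#' @return normalized character vector
#' @export
normalize_name <- function(x) {
  gsub("[-/_[:space:]]+", "", tolower(x))
}

# Unordered-pair key from two normalized names.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

empty_token_df <- function() {
  data.frame(index = integer(), text = character(), lemma = character(),
             pos = character(), start = integer(), end = integer())
}

empty_edge_df <- function() {
  data.frame(label = character(), gov = integer(), dep = integer())
}

empty_arg_df <- function() {
  data.frame(label = character(), pred = integer(), arg = integer(),
             provenance = character())
}

empty_sem_df <- function() {
  data.frame(label = character(), src = integer(), tgt = integer())
}

empty_mention_df <- function() {
  data.frame(mention_id = character(), text = character(), start = integer(),
             end = integer(), entity_type = character())
}

empty_pair_df <- function() {
  data.frame(doc_id = character(), sentence_index = integer(),
             mention_a = character(), mention_b = character(),
             name_a = character(), name_b = character(),
             trigger = character(), rule_id = character())
}

# Stable row-deduplication of a data frame by a key built from some columns.
dedup_df <- function(df, cols) {
  if (nrow(df) == 0L) return(df)
  key <- do.call(paste, c(df[cols], sep = "\r"))
  df[!duplicated(key), , drop = FALSE]
}

# rbind that tolerates zero-row pieces and resets row names.
rbind_df <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}
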