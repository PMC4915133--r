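#' Precision / recall / F-value from confusion counts
#'
#' \eqn{P = 100 \cdot tp/(tp+fp)}, \eqn{R = 100 \cdot tp/(tp+fn)},
#' \eqn{F = 2PR/(P+R)}; 0/0 cases are defined as 0. Values are percentages;
#' reporting rounds half-up to one decimal, matching the convention of
#' published PPI evaluation tables.
#'
#' @param tp,fp,fn non-negative integer counts; alternatively pass a list
#'   with those names as \code{tp}
#' @param digits decimal places for reporting (default 1); use \code{NULL}
#'   for unrounded values
#' @return named list with \code{precision}, \code{recall}, \code{f_value}
#' @export
score_counts <- function(tp, fp = NULL, fn = NULL, digits = 1) {
  if (is.list(tp)) {
    fp <- tp$fp; fn <- tp$fn; tp <- tp$tp
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  out <- list(precision = p, recall = r, f_value = f)
  if (!is.null(digits)) out <- lapply(out, round_half_up, digits = digits)
  out
}

#' Score predicted PPI pairs against gold name pairs
#'
#' Unique-pair matching at document level: a predicted pair matches a gold
#' pair iff both normalized names match, order-free. Both sides are
#' normalized with [normalize_name()]; an optional alias map (normalized
#' alias -> normalized canonical name, e.g. from document-wide abbreviation
#' pairs) is applied to both sides first.
#'
#' @param predicted PPI-pair data frame (needs \code{name_a}, \code{name_b};
#'   \code{doc_id} used when present)
#' @param gold data frame with columns \code{name_a}, \code{name_b} and
#'   optionally \code{doc_id}
#' @param aliases optional named character vector mapping normalized alias to
#'   normalized canonical form
#' @return list with \code{tp}, \code{fp}, \code{fn}
#' @export
score_pairs <- function(predicted, gold, aliases = NULL) {
  canon <- function(x) {
    n <- normalize_name(x)
    if (!is.null(aliases)) {
      hit <- n %in% names(aliases)
      n[hit] <- aliases[n[hit]]
    }
    n
  }
  keyed <- function(df) {
    if (nrow(df) == 0L) return(character(0))
    doc <- if ("doc_id" %in% names(df)) df$doc_id else ""
    unique(paste(doc, pair_key(canon(df$name_a), canon(df$name_b))))
  }
  pk <- keyed(predicted)
  gk <- keyed(gold)
  list(tp = length(intersect(pk, gk)),
       fp = length(setdiff(pk, gk)),
       fn = length(setdiff(gk, pk)))
}

#' Score predicted PPI sentences against gold sentence sets
#'
#' Per-sentence binary comparison summed over documents: each predicted and
#' gold side is a set of (document, sentence index) identifiers.
#'
#' @param predicted data frame with columns \code{doc_id},
#'   \code{sentence_index} (or an integer vector for a single document)
#' @param gold same format as \code{predicted}
#' @return list with \code{tp}, \code{fp}, \code{fn}
#' @export
score_sentences <- function(predicted, gold) {
  keyed <- function(x) {
    if (is.data.frame(x)) {
      if (nrow(x) == 0L) return(character(0))
      unique(paste(x$doc_id, x$sentence_index))
    } else {
      if (length(x) == 0L) return(character(0))
      unique(paste("", x))
    }
  }
  pk <- keyed(predicted)
  gk <- keyed(gold)
  list(tp = length(intersect(pk, gk)),
       fp = length(setdiff(pk, gk)),
       fn = length(setdiff(gk, pk)))
}

#' Read a gold pairs TSV (doc_id, name_a, name_b)
#'
#' @param path TSV path with a header line
#' @return data frame
#' @export
read_gold_pairs <- function(path) {
  utils::read.delim(path, colClasses = "character")
}

#' Read a gold sentences TSV (doc_id, sentence_index)
#'
#' @param path TSV path with a header line
#' @return data frame
#' @export
read_gold_sentences <- function(path) {
  out <- utils::read.delim(path)
  out$doc_id <- as.character(out$doc_id)
  out$sentence_index <- as.integer(out$sentence_index)
  out
}

#' Format a P/R/F report row
#'
#' @param label row label
#' @param counts list with \code{tp}, \code{fp}, \code{fn}
#' @return one-row data frame (label, tp, fp, fn, precision, recall, f_value)
#' @export
prf_row <- function(label, counts) {
  s <- score_counts(counts)
  data.frame(label = label, tp = counts$tp, fp = counts$fp, fn = counts$fn,
             precision = s$precision, recall = s$recall, f_value = s$f_value)
}
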