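# Rule-based recall-boosting post-processing and CDI ranking.
#
# Both heuristics are monotone at token level: a token labelled chemical is
# never relabelled back, so the chemical token set can only grow.

#' Post-processing configuration
#'
#' @param t1 Confidence threshold: only `O` tokens with marginal confidence
#'   strictly below `t1` are candidates for composition-based relabelling.
#'   Default 0.93 (the setting that optimises precision and F1).
#' @param t2 Composition threshold: a candidate is relabelled only if its
#'   chemical segment composition is strictly greater than `t2`. Default 0.9.
#' @param enable_abbrev Run abbreviation recognition?
#' @param enable_composition Run composition-based relabelling?
#' @return A `chem_relabel_config` list.
#' @export
relabel_config <- function(t1 = 0.93, t2 = 0.9, enable_abbrev = TRUE,
                           enable_composition = TRUE) {
  stopifnot(t1 >= 0, t1 <= 1, t2 >= 0, t2 <= 1)
  structure(list(t1 = t1, t2 = t2, enable_abbrev = enable_abbrev,
                 enable_composition = enable_composition),
            class = "chem_relabel_config")
}

#' Verify an abbreviation candidate against its long form
#'
#' True iff every character of the candidate occurs, in order but not
#' necessarily contiguously, within the entity text (case-insensitive).
#'
#' @param candidate Abbreviation token surface.
#' @param entity Long-form mention text.
#' @return Logical.
#' @examples
#' verify_abbreviation("STMP", "sodium trimetaphosphate")  # TRUE
#' @export
verify_abbreviation <- function(candidate, entity) {
  stopifnot(nzchar(candidate), nzchar(entity))
  cc <- chars(tolower(candidate))
  ec <- chars(tolower(entity))
  j <- 1L
  for (ch in cc) {
    while (j <= length(ec) && ec[j] != ch) j <- j + 1L
    if (j > length(ec)) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

#' Abbreviation recognition over a document's token sequence
#'
#' For each recognised mention ending at token `t_i` such that `t_(i+1)` is
#' `"("`, `t_(i+3)` is `")"` and `t_(i+2)` is labelled non-chemical, the
#' token `t_(i+2)` is a candidate abbreviation of the mention; if its
#' characters occur sequentially within the mention text, *all* occurrences
#' of that surface form in the document are relabelled `B` (each a
#' single-token mention). Labels are only ever added, never removed.
#'
#' @param surfaces Token surfaces for the whole document (all sentences,
#'   in order).
#' @param labels BIO labels parallel to `surfaces`.
#' @return Updated label vector.
#' @export
recognise_abbreviations <- function(surfaces, labels) {
  n <- length(surfaces)
  stopifnot(length(labels) == n)
  captured <- character()
  for (i in seq_len(n)) {
    if (labels[i] == "O") next
    if (i + 1L <= n && labels[i + 1L] != "O") next  # mention continues
    if (i + 3L > n) next
    if (surfaces[i + 1L] != "(" || surfaces[i + 3L] != ")") next
    if (labels[i + 2L] != "O") next
    # reconstruct the mention text ending at token i
    s <- i
    while (s > 1L && labels[s] == "I") s <- s - 1L
    entity <- paste(surfaces[s:i], collapse = " ")
    cand <- surfaces[i + 2L]
    if (verify_abbreviation(cand, entity))
      captured <- c(captured, cand)
  }
  if (length(captured))
    labels[labels == "O" & surfaces %in% captured] <- "B"
  labels
}

#' Chemical composition-based token relabelling
#'
#' Tokens labelled `O` with marginal confidence strictly below `t1` are
#' inspected: if the chemical segment composition ratio of the surface is
#' strictly greater than `t2`, the token is relabelled `B` (a single-token
#' mention; adjacent relabelled tokens are not merged). `O` to chemical is
#' the only permitted change.
#'
#' @param surfaces Token surfaces.
#' @param labels BIO labels parallel to `surfaces`.
#' @param confidences Per-token marginal confidences.
#' @param segdict Segment dictionary from [load_segment_dictionary()].
#' @param cfg A [relabel_config()].
#' @return Updated label vector.
#' @export
relabel_by_composition <- function(surfaces, labels, confidences, segdict,
                                   cfg = relabel_config()) {
  n <- length(surfaces)
  stopifnot(length(labels) == n, length(confidences) == n)
  for (i in seq_len(n)) {
    if (labels[i] != "O") next
    if (!(confidences[i] < cfg$t1)) next
    if (!nzchar(surfaces[i])) next
    if (composition_ratio(surfaces[i], segdict) > cfg$t2)
      labels[i] <- "B"
  }
  labels
}

#' Rank unique mention strings for document indexing (CDI)
#'
#' Deduplicates predicted mentions by exact surface string (case-sensitive),
#' keeping each string's maximum confidence, then sorts descending by
#' confidence with ties broken by string.
#'
#' @param mentions Mention data frame for one document, confidences set.
#' @return Data frame with columns `text`, `confidence` in rank order.
#' @export
rank_cdi <- function(mentions) {
  if (is.null(mentions) || nrow(mentions) == 0)
    return(data.frame(text = character(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  conf <- tapply(mentions$confidence, mentions$text, max)
  out <- data.frame(text = names(conf), confidence = as.numeric(conf),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$confidence, out$text), , drop = FALSE]
  rownames(out) <- NULL
  out
}
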