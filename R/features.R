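# Per-token feature extraction.
#
# Two tiers: a default, weakly chemical-indicative set (character n-grams,
# word/lemma/POS context n-grams within a distance of two, chunk information,
# orthographic flags) and a knowledge-rich set that adds Greek-character
# flags, word shapes, dictionary-label context features, affix matches,
# basic-segment counts and element symbol flags. All features are
# presence-valued strings namespaced by extractor.

GREEK_NAMES <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
                 "theta", "iota", "kappa", "lambda", "mu", "nu", "xi",
                 "omicron", "pi", "rho", "sigma", "tau", "upsilon", "phi",
                 "chi", "psi", "omega")

#' Character n-grams of a token
#'
#' All contiguous substrings of length `n`, as a set (duplicates collapse).
#'
#' @param token Token surface.
#' @param n Substring length (2, 3 or 4).
#' @return Character vector of unique n-grams; empty when the token is
#'   shorter than `n`.
#' @examples
#' char_ngrams("GSK214a", 2)  # GS SK K2 21 14 4a
#' @export
char_ngrams <- function(token, n) {
  len <- nchar(token)
  if (len < n) return(character())
  unique(vapply(seq_len(len - n + 1L),
                function(i) substr(token, i, i + n - 1L), character(1)))
}

#' Word shape of a token
#'
#' Digits map to `0`, uppercase letters to `A`, lowercase letters to `a`,
#' everything else to `_`, per code point. The full shape retains every
#' character; the brief shape collapses runs of identical shape characters.
#'
#' @param token Token surface.
#' @return Named character vector with elements `full` and `brief`.
#' @examples
#' word_shape("10-amino-20(S)-camptothecin")
#' @export
word_shape <- function(token) {
  cs <- chars(token)
  sh <- ifelse(grepl("^[0-9]$", cs), "0",
        ifelse(grepl("^[A-Z]$", cs), "A",
        ifelse(grepl("^[a-z]$", cs), "a", "_")))
  full <- paste(sh, collapse = "")
  brief <- if (length(sh)) paste(rle(sh)$values, collapse = "") else ""
  c(full = full, brief = brief)
}

ORTHO_TESTS <- list(
  initUpper    = function(t) grepl("^[A-Z]", t),
  allDigits    = function(t) nzchar(t) && grepl("^[0-9]+$", t),
  hasDigit     = function(t) grepl("[0-9]", t),
  allAlnum     = function(t) nzchar(t) && grepl("^[A-Za-z0-9]+$", t),
  upperDigits  = function(t) nzchar(t) && grepl("^[A-Z0-9]+$", t) &&
                             grepl("[A-Z]", t),
  allUpper     = function(t) nzchar(t) && grepl("^[A-Z]+$", t),
  noLower      = function(t) nzchar(t) && !grepl("[a-z]", t),
  nonInitUpper = function(t) grepl(".[A-Z]", t),
  twoUpper     = function(t) grepl("[A-Z][A-Z]", t),
  greekName    = function(t) any(vapply(GREEK_NAMES, grepl, logical(1),
                                        x = tolower(t), fixed = TRUE)),
  comma        = function(t) grepl(",", t, fixed = TRUE),
  fullStop     = function(t) grepl(".", t, fixed = TRUE),
  hyphen       = function(t) grepl("-", t, fixed = TRUE),
  slash        = function(t) grepl("/", t, fixed = TRUE),
  openSquare   = function(t) grepl("[", t, fixed = TRUE),
  closeSquare  = function(t) grepl("]", t, fixed = TRUE),
  openParen    = function(t) grepl("(", t, fixed = TRUE),
  closeParen   = function(t) grepl(")", t, fixed = TRUE),
  semicolon    = function(t) grepl(";", t, fixed = TRUE),
  percent      = function(t) grepl("%", t, fixed = TRUE),
  apostrophe   = function(t) grepl("'", t, fixed = TRUE)
)

#' Orthographic features of a token
#'
#' Twenty-one boolean symbol-composition tests (initial capital, digit
#' content, bracket/punctuation occurrence, Greek letter *names* as
#' substrings, ...) plus a flag for Unicode Greek characters
#' (\\u0370-\\u03ff, \\u1f00-\\u1fff).
#'
#' @param token Token surface.
#' @return Character vector of the feature keys whose test fired.
#' @export
orthographic_features <- function(token) {
  if (!nzchar(token)) return(character())
  fired <- names(ORTHO_TESTS)[vapply(ORTHO_TESTS, function(f) isTRUE(f(token)),
                                     logical(1))]
  feats <- paste0("orth=", fired)
  if (grepl("[\u0370-\u03ff\u1f00-\u1fff]", token))
    feats <- c(feats, "orth=greekChar")
  feats
}

#' Context n-gram features
#'
#' Surface, normalised-shape, lemma, POS and lemma:POS unigrams for offsets
#' -2..+2 around the active token, bigrams over adjacent offset pairs inside
#' that window, plus the chunk tag of the active token and the surface form
#' of the final token of its enclosing chunk.
#'
#' @param tokens Annotated token data frame (columns `surface`, `lemma`,
#'   `pos`, `chunk`).
#' @param index 1-based position of the active token.
#' @param window Context half-width (fixed at 2 by the feature design).
#' @return Character vector of feature strings.
#' @export
context_ngrams <- function(tokens, index, window = 2L) {
  n <- nrow(tokens)
  surf <- tokens$surface
  nrm <- vapply(surf, function(t) word_shape(t)[["full"]], character(1),
                USE.NAMES = FALSE)
  lem <- tokens$lemma
  pos <- tokens$pos
  lp <- paste0(lem, ":", pos)
  views <- list(w = surf, wn = nrm, lm = lem, pos = pos, lmpos = lp)
  feats <- character()
  offs <- seq.int(-window, window)
  for (o in offs) {
    p <- index + o
    if (p < 1L || p > n) next
    for (v in names(views))
      feats <- c(feats, sprintf("%s[%d]=%s", v, o, views[[v]][p]))
  }
  for (o in head(offs, -1L)) {
    p <- index + o
    if (p < 1L || p + 1L > n) next
    for (v in names(views))
      feats <- c(feats, sprintf("%s[%d,%d]=%s|%s", v, o, o + 1L,
                                views[[v]][p], views[[v]][p + 1L]))
  }
  # chunk information: tag of the active token, surface of the last token of
  # its enclosing chunk
  ch <- tokens$chunk[index]
  feats <- c(feats, paste0("chunk=", ch))
  if (ch != "O") {
    last <- index
    while (last < n && startsWith(tokens$chunk[last + 1L], "I-")) last <- last + 1L
    feats <- c(feats, paste0("chunkend=", surf[last]))
  }
  feats
}

segment_bucket <- function(count) if (count >= 5L) "5+" else as.character(count)

#' Bundle the matching resources for feature assembly
#'
#' @param lexicons List of [compile_lexicon()] objects (the five dictionary
#'   slots; any number is accepted).
#' @param affixes [load_affixes()] object.
#' @param elements Character vector from [load_elements()].
#' @param segdict [load_segment_dictionary()] object.
#' @return Object of class `chem_resources`.
#' @export
chem_resources <- function(lexicons = list(), affixes = load_affixes(),
                           elements = load_elements(),
                           segdict = load_segment_dictionary()) {
  structure(list(lexicons = lexicons, affixes = affixes,
                 elements = elements, segdict = segdict),
            class = "chem_resources")
}

#' Assemble the full feature vector for one token
#'
#' With `knowledge_rich = FALSE` only the default, weakly chemical-indicative
#' features are produced: character n-grams (n = 2, 3, 4), context n-grams
#' and the 21 orthographic flags. With `knowledge_rich = TRUE` the vector
#' additionally contains the Greek-character flag, full and brief word
#' shapes, dictionary-label context features for every lexicon, affix
#' matches, the (bucketed) basic-segment count and the element-symbol flag.
#' The enriched set is a superset of the default set by construction, and
#' extraction is a pure function of its inputs.
#'
#' @param tokens Annotated token data frame for one sentence.
#' @param index Active token position (1-based).
#' @param resources [chem_resources()] bundle (required when
#'   `knowledge_rich = TRUE`).
#' @param knowledge_rich Enable the chemical knowledge-rich extractors?
#' @return Character vector of unique feature strings.
#' @export
assemble_features <- function(tokens, index, resources = NULL,
                              knowledge_rich = TRUE) {
  tok <- tokens$surface[index]
  feats <- c(
    paste0("chr2=", char_ngrams(tok, 2L)),
    paste0("chr3=", char_ngrams(tok, 3L)),
    paste0("chr4=", char_ngrams(tok, 4L)),
    context_ngrams(tokens, index),
    orthographic_features(tok))
  greek_flag <- "orth=greekChar"
  if (!knowledge_rich)
    return(unique(setdiff(feats, greek_flag)))
  if (is.null(resources))
    stop("knowledge-rich features require a chem_resources bundle")
  ws <- word_shape(tok)
  feats <- c(feats, paste0("wsF=", ws[["full"]]), paste0("wsB=", ws[["brief"]]))
  if (length(resources$lexicons)) {
    norm <- normalise_form(tokens$lemma)
    for (lex in resources$lexicons) {
      labels <- tag_lexicon(norm, lex)
      feats <- c(feats,
                 lexicon_features(labels, tokens$surface, index, lex$name))
    }
  }
  am <- match_affixes(tok, resources$affixes)
  hit <- !is.na(am)
  feats <- c(feats, sprintf("%s=%s", names(am)[hit], am[hit]))
  feats <- c(feats,
             paste0("seg=", segment_bucket(count_segments(tok,
                                                          resources$segdict))))
  if (match_element_symbol(tok, resources$elements))
    feats <- c(feats, "elem=1")
  unique(feats)
}
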