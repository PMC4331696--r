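# Dictionary compilation, longest-match BIO tagging, affix and element
# symbol matching.

#' Normalise a token form
#'
#' Alphabetic characters are lower-cased, digits become `0` and every other
#' character becomes `_`. The mapping is per code point, so length is
#' preserved, and it is idempotent. The same normalisation is applied to
#' dictionary entries at compile time and to input text at match time.
#'
#' @param form Character vector.
#' @return Normalised character vector of the same length.
#' @examples
#' normalise_form("HES-HEMA")  # "hes_hema"
#' normalise_form("GSK214a")   # "gsk000a"
#' @export
normalise_form <- function(form) {
  x <- tolower(form)
  x <- gsub("[0-9]", "0", x)
  gsub("[^a-z0]", "_", x, perl = TRUE)
}

#' Compile a lexicon for longest-match tagging
#'
#' Entries are whitespace-tokenised (multi-word entries allowed) and each
#' word is normalised with [normalise_form()]. Empty entries are dropped.
#'
#' @param entries Character vector of dictionary entries, or a file path when
#'   `from_file = TRUE` (one entry per line, UTF-8).
#' @param name Lexicon name used to namespace its features (e.g. `"CTD"`).
#' @param from_file Read `entries` from disk?
#' @return An object of class `chem_lexicon`.
#' @export
compile_lexicon <- function(entries, name = "lex", from_file = FALSE) {
  if (from_file) entries <- readLines(entries, encoding = "UTF-8", warn = FALSE)
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  toks <- lapply(strsplit(entries, "[[:space:]]+"), normalise_form)
  keys <- unique(vapply(toks, paste, character(1), collapse = " "))
  keys <- keys[nzchar(keys)]
  lens <- vapply(strsplit(keys, " ", fixed = TRUE), length, integer(1))
  structure(list(name = name, keys = keys, max_len = max(c(1L, lens)),
                 set = stats::setNames(rep(TRUE, length(keys)), keys)),
            class = "chem_lexicon")
}

#' @export
print.chem_lexicon <- function(x, ...) {
  cat(sprintf("<chem_lexicon %s: %d entries, longest %d token(s)>\n",
              x$name, length(x$keys), x$max_len))
  invisible(x)
}

#' Tag a token sequence against a lexicon
#'
#' Left-to-right greedy longest match between the normalised token sequence
#' and the compiled entries. A matched span is labelled `B` then `I...`;
#' everything else is `O`. Matching starts again after the end of a match,
#' so the result is always a valid BIO sequence.
#'
#' @param norm_tokens Character vector of tokens already normalised with
#'   [normalise_form()] (applied to lemmas, matching the compile-time
#'   treatment of entries).
#' @param lex A [compile_lexicon()] object.
#' @return Character vector of BIO labels, one per token.
#' @export
tag_lexicon <- function(norm_tokens, lex) {
  n <- length(norm_tokens)
  labels <- rep("O", n)
  if (n == 0L || length(lex$keys) == 0L) return(labels)
  i <- 1L
  while (i <= n) {
    best <- 0L
    for (len in seq.int(min(lex$max_len, n - i + 1L), 1L)) {
      key <- paste(norm_tokens[i:(i + len - 1L)], collapse = " ")
      if (isTRUE(unname(lex$set[key]))) { best <- len; break }
    }
    if (best > 0L) {
      labels[i] <- "B"
      if (best > 1L) labels[(i + 1L):(i + best - 1L)] <- "I"
      i <- i + best
    } else i <- i + 1L
  }
  labels
}

#' Dictionary-label context features
#'
#' For the active token, emits unigrams and bigrams of the per-lexicon BIO
#' labels within a distance of 2, and the same n-grams combined with the
#' corresponding surface forms. For the token *starch* tagged `I` after
#' *hydroxyethyl* `B` preceded by *on* `O`, the features include the
#' surface:label bigrams `{on:O, hydroxyethyl:B}` and
#' `{hydroxyethyl:B, starch:I}` and the label bigrams `{O, B}` and `{B, I}`.
#'
#' @param labels BIO labels from [tag_lexicon()], aligned with `surfaces`.
#' @param surfaces Token surface forms.
#' @param index 1-based position of the active token.
#' @param name Lexicon name used in the feature namespace.
#' @param window Context half-width (fixed at 2 by the feature design).
#' @return Character vector of feature strings.
#' @export
lexicon_features <- function(labels, surfaces, index, name = "lex",
                             window = 2L) {
  n <- length(labels)
  feats <- character()
  offs <- seq.int(-window, window)
  for (o in offs) {
    p <- index + o
    if (p < 1L || p > n) next
    feats <- c(feats,
               sprintf("dict%s:u[%d]=%s", name, o, labels[p]),
               sprintf("dict%s:wu[%d]=%s:%s", name, o, surfaces[p], labels[p]))
  }
  for (o in head(offs, -1L)) {
    p <- index + o
    if (p < 1L || p + 1L > n) next
    feats <- c(feats,
               sprintf("dict%s:b[%d,%d]=%s|%s", name, o, o + 1L,
                       labels[p], labels[p + 1L]),
               sprintf("dict%s:wb[%d,%d]=%s:%s|%s:%s", name, o, o + 1L,
                       surfaces[p], labels[p], surfaces[p + 1L], labels[p + 1L]))
  }
  feats
}

#' Load affix lists
#'
#' Chemical prefixes and suffixes of length two to four, one per line,
#' in separate files. Entries are lower-cased; anything outside length
#' 2-4 is rejected.
#'
#' @param prefix_path,suffix_path Paths to the affix files. Defaults to the
#'   fixture lists shipped with the package.
#' @return An object of class `chem_affixes`: lists `prefix` and `suffix`,
#'   each partitioned by length (`"2"`, `"3"`, `"4"`).
#' @export
load_affixes <- function(
    prefix_path = system.file("extdata", "prefixes.txt", package = "chemner"),
    suffix_path = system.file("extdata", "suffixes.txt", package = "chemner")) {
  read_side <- function(path) {
    x <- tolower(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)))
    x <- x[nzchar(x)]
    if (any(nchar(x) < 2 | nchar(x) > 4))
      stop("affix lengths must be in 2..4: ",
           paste(x[nchar(x) < 2 | nchar(x) > 4], collapse = ", "))
    split(x, as.character(nchar(x)))
  }
  structure(list(prefix = read_side(prefix_path),
                 suffix = read_side(suffix_path)),
            class = "chem_affixes")
}

#' Match a token against the affix lists
#'
#' Case-insensitive: the token is lower-cased before its boundary substrings
#' are looked up (chemical affixes appear capitalised sentence-initially).
#'
#' @param token Token surface (non-empty).
#' @param affixes A [load_affixes()] object.
#' @return Named character vector with entries `prefix2`..`prefix4`,
#'   `suffix2`..`suffix4`: the matched affix, or `NA` when the boundary
#'   substring of that size is not in the list (or the token is too short).
#' @export
match_affixes <- function(token, affixes) {
  stopifnot(nzchar(token))
  lt <- tolower(token)
  n <- nchar(lt)
  out <- stats::setNames(rep(NA_character_, 6),
                         c(paste0("prefix", 2:4), paste0("suffix", 2:4)))
  for (size in 2:4) {
    if (n < size) next
    p <- substr(lt, 1, size)
    if (p %in% affixes$prefix[[as.character(size)]])
      out[[paste0("prefix", size)]] <- p
    s <- substr(lt, n - size + 1L, n)
    if (s %in% affixes$suffix[[as.character(size)]])
      out[[paste0("suffix", size)]] <- s
  }
  out
}

#' Load the element symbol list
#'
#' @param path One symbol per line; defaults to the 118-symbol periodic
#'   table shipped with the package.
#' @return Character vector of symbols.
#' @export
load_elements <- function(
    path = system.file("extdata", "elements.txt", package = "chemner")) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x)]
}

#' Is a token an element symbol?
#'
#' Exact, case-sensitive membership: `"Fe"` matches, `"fe"` and `"NO"`
#' (nitric oxide is not a symbol; nobelium is `"No"`) do not.
#'
#' @param token Token surface.
#' @param elements Symbol list from [load_elements()].
#' @return Logical.
#' @export
match_element_symbol <- function(token, elements) {
  token %in% elements
}
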