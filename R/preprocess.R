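# Sentence splitting and tokenisation tuned for chemical text.
#
# The "scientific" splitter accepts sentence boundaries even when the next
# sentence starts with a lower-case character (protein names such as p53);
# the "general" splitter requires an upper-case or digit start. The
# "chemistry" tokeniser keeps long systematic names (digits, commas, hyphens,
# balanced brackets) intact as single tokens while still isolating sentence
# punctuation and unbalanced parentheses; the "general" tokeniser splits at
# every punctuation character.

# Abbreviations after which a full stop never ends a sentence.
SPLIT_EXCEPTIONS <- c("e.g", "i.e", "et al", "etc", "vs", "cf", "Fig", "fig",
                      "Dr", "no", "No")

# Plain-English words that, after a hyphen, are detached from a preceding
# chemical-like fragment ("GSK214a-induced" -> "GSK214a", "-induced").
HYPHEN_SUFFIXES <- c("induced", "treated", "mediated", "based", "dependent",
                     "related", "containing", "derived", "like", "specific",
                     "stimulated", "activated", "coated", "free", "rich",
                     "bound", "linked", "labelled", "labeled", "conjugated",
                     "sensitive", "resistant", "associated", "binding")

chars <- function(text) strsplit(text, "", fixed = FALSE)[[1]]

#' Split section text into sentences
#'
#' Boundaries are placed after runs of `.`, `!` or `?` that are followed by
#' whitespace, unless the full stop terminates a known abbreviation
#' (e.g., i.e., et al., ...). In `"scientific"` mode the next sentence may
#' start with any character; in `"general"` mode the boundary is accepted
#' only if the next non-space character is upper-case or a digit.
#'
#' @param text Section text (may be empty).
#' @param mode `"scientific"` (default) or `"general"`.
#' @return Data frame with 0-based half-open columns `start`, `end` and the
#'   covered `text`, one row per sentence. Spans are trimmed to non-whitespace.
#' @export
split_sentences <- function(text, mode = c("scientific", "general")) {
  mode <- match.arg(mode)
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  cs <- chars(text)
  n <- length(cs)
  boundaries <- integer()  # index of last char of each sentence (1-based)
  i <- 1L
  while (i <= n) {
    if (cs[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && cs[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      after_ws <- j == n || grepl("^\\s$", cs[j + 1L])
      if (after_ws) {
        ok <- TRUE
        if (cs[i] == ".") {
          # look back at the word preceding the stop
          k <- i - 1L
          while (k >= 1L && !grepl("^\\s$", cs[k])) k <- k - 1L
          prev <- paste(cs[seq.int(k + 1L, max(k + 1L, i - 1L))], collapse = "")
          if (i - 1L < k + 1L) prev <- ""
          if (prev %in% SPLIT_EXCEPTIONS ||
              paste0("et ", prev) %in% SPLIT_EXCEPTIONS)
            ok <- FALSE
          # "et al." style: check two preceding words
          if (ok && nzchar(prev)) {
            k2 <- k - 1L
            while (k2 >= 1L && !grepl("^\\s$", cs[k2])) k2 <- k2 - 1L
            if (k - 1L >= k2 + 1L) {
              prev2 <- paste(cs[seq.int(k2 + 1L, k - 1L)], collapse = "")
              if (paste(prev2, prev) %in% SPLIT_EXCEPTIONS) ok <- FALSE
            }
          }
        }
        if (ok && mode == "general" && j < n) {
          m <- j + 1L
          while (m <= n && grepl("^\\s$", cs[m])) m <- m + 1L
          if (m <= n && !grepl("^[[:upper:][:digit:]]$", cs[m])) ok <- FALSE
        }
        if (ok) boundaries <- c(boundaries, j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(boundaries) == 0L || boundaries[length(boundaries)] != n)
    boundaries <- c(boundaries, n)
  starts <- c(1L, head(boundaries, -1L) + 1L)
  out <- empty
  for (s in seq_along(boundaries)) {
    a <- starts[s]; b <- boundaries[s]
    while (a <= b && grepl("^\\s$", cs[a])) a <- a + 1L
    while (b >= a && grepl("^\\s$", cs[b])) b <- b - 1L
    if (a > b) next
    out <- rbind(out, data.frame(
      start = a - 1L, end = b,
      text = paste(cs[a:b], collapse = ""), stringsAsFactors = FALSE))
  }
  out
}

is_punct_char <- function(ch) grepl("^[^[:alnum:][:space:]]$", ch)

OPENERS <- c("(", "[", "{")
CLOSERS <- c(")", "]", "}")
TERMINALS <- c(".", ",", ";", ":", "!", "?")

# Split one whitespace-delimited chunk under chemistry rules.
# Returns integer matrix of (start,end) offsets relative to the chunk (1-based
# inclusive), in textual order.
split_chunk_chemistry <- function(cs) {
  n <- length(cs)
  if (n == 0L) return(matrix(integer(), ncol = 2))
  a <- 1L; b <- n
  pre <- list(); post <- list()
  # position of the closer matching the opener at position `at`, or NA
  match_closer <- function(at, to) {
    opener <- cs[at]; closer <- CLOSERS[match(opener, OPENERS)]
    depth <- 0L
    for (k in seq.int(at, to)) {
      if (cs[k] == opener) depth <- depth + 1L
      else if (cs[k] == closer) {
        depth <- depth - 1L
        if (depth == 0L) return(k)
      }
    }
    NA_integer_
  }
  repeat {
    if (a >= b) break
    if (cs[b] %in% TERMINALS) {
      # trailing sentence punctuation detaches
      post[[length(post) + 1L]] <- c(b, b)
      b <- b - 1L
      next
    }
    if (cs[a] %in% OPENERS) {
      # a wrapping opener detaches ("(STMP)" -> "(" "STMP" ")"); an opener
      # whose matching closer sits mid-chunk is part of a chemical name
      # ("(E/Z)-Goniothalamin") and the chunk stays whole
      mc <- match_closer(a, b)
      if (is.na(mc) || mc == b) {
        pre[[length(pre) + 1L]] <- c(a, a)
        a <- a + 1L
        next
      }
    }
    if (cs[b] %in% CLOSERS) {
      core <- cs[a:(b - 1L)]
      opener <- OPENERS[match(cs[b], CLOSERS)]
      if (sum(core == opener) <= sum(core == cs[b])) {
        # no unmatched opener inside: the closer is detachable punctuation
        post[[length(post) + 1L]] <- c(b, b)
        b <- b - 1L
        next
      }
    }
    break
  }
  spans <- list()
  if (a <= b) {
    # hyphen + plain-word suffix split, keeping the hyphen on the suffix
    core <- cs[a:b]
    cut <- NA_integer_
    hy <- which(core == "-")
    for (h in hy) {
      if (h == 1L || h == length(core)) next
      restl <- tolower(paste(core[(h + 1L):length(core)], collapse = ""))
      if (restl %in% HYPHEN_SUFFIXES) { cut <- h; break }
    }
    if (!is.na(cut)) {
      spans <- list(c(a, a + cut - 2L), c(a + cut - 1L, b))
    } else spans <- list(c(a, b))
  }
  parts <- c(pre, spans, rev(post))
  do.call(rbind, parts)
}

split_chunk_general <- function(cs) {
  n <- length(cs)
  spans <- list()
  i <- 1L
  while (i <= n) {
    if (is_punct_char(cs[i])) {
      spans[[length(spans) + 1L]] <- c(i, i)
      i <- i + 1L
    } else {
      j <- i
      while (j < n && !is_punct_char(cs[j + 1L])) j <- j + 1L
      spans[[length(spans) + 1L]] <- c(i, j)
      i <- j + 1L
    }
  }
  do.call(rbind, spans)
}

#' Tokenise a sentence
#'
#' In `"chemistry"` mode, whitespace-delimited chunks are kept intact —
#' including digits, commas, hyphens and balanced internal brackets, so
#' systematic names like `4,9-Diazadodecane-1,12-diamine` survive as one
#' token — except that (i) sentence punctuation and unbalanced brackets at
#' chunk edges become separate tokens and (ii) a hyphen joining a chemical
#' fragment to a plain English word splits before the hyphen, which stays
#' attached to the word (`"GSK214a-induced"` -> `"GSK214a"`, `"-induced"`).
#' In `"general"` mode every punctuation character is a separate token.
#'
#' @param sentence One row of [split_sentences()] output, or a list/data frame
#'   with fields `text` and `start` (offset of the sentence within the
#'   section).
#' @param mode `"chemistry"` (default) or `"general"`.
#' @return Token data frame with columns `surface`, `start`, `end`
#'   (0-based half-open, in section coordinates).
#' @export
tokenise <- function(sentence, mode = c("chemistry", "general")) {
  mode <- match.arg(mode)
  text <- sentence$text[1]
  base <- as.integer(sentence$start[1])
  cs <- chars(text)
  n <- length(cs)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (grepl("^\\s$", cs[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !grepl("^\\s$", cs[j + 1L])) j <- j + 1L
    chunk <- cs[i:j]
    spans <- if (mode == "chemistry") split_chunk_chemistry(chunk)
             else split_chunk_general(chunk)
    for (r in seq_len(nrow(spans))) {
      s <- spans[r, 1]; e <- spans[r, 2]
      out[[length(out) + 1L]] <- data.frame(
        surface = paste(chunk[s:e], collapse = ""),
        start = base + i - 1L + s - 1L,
        end = base + i - 1L + e, stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Attach lemma, POS and chunk annotations
#'
#' The tagger is pluggable: any function taking a character vector of token
#' surfaces and returning a list with equal-length character vectors `lemma`,
#' `pos` and `chunk` can be used, so a statistical biomedical tagger can be
#' substituted for the built-in deterministic [fallback_tagger()].
#'
#' @param tokens Token data frame from [tokenise()].
#' @param tagger Tagger function; defaults to [fallback_tagger].
#' @return `tokens` with `lemma`, `pos`, `chunk` columns added.
#' @export
tag_tokens <- function(tokens, tagger = fallback_tagger) {
  ann <- tagger(tokens$surface)
  for (f in c("lemma", "pos", "chunk")) {
    if (length(ann[[f]]) != nrow(tokens))
      stop(sprintf("tagger returned %d '%s' annotations for %d tokens",
                   length(ann[[f]]), f, nrow(tokens)))
    tokens[[f]] <- ann[[f]]
  }
  tokens
}

rule_pos <- function(w) {
  lw <- tolower(w)
  if (grepl("^[^[:alnum:]]+$", w) && !startsWith(w, "-")) return(substr(w, 1, 1))
  if (lw %in% c("the", "a", "an")) return("DT")
  if (lw %in% c("it", "he", "she", "they", "we", "i", "you")) return("PRP")
  if (lw %in% c("in", "of", "on", "with", "for", "at", "by", "from",
                "into", "during", "against")) return("IN")
  if (lw == "to") return("TO")
  if (lw %in% c("and", "or", "but")) return("CC")
  if (lw %in% c("was", "were", "did", "had")) return("VBD")
  if (lw %in% c("is", "has")) return("VBZ")
  if (lw %in% c("are", "have", "do")) return("VBP")
  if (lw %in% c("not", "significantly", "daily", "quickly")) return("RB")
  if (grepl("^[0-9]", w)) return("CD")
  if (startsWith(w, "-")) return("JJ")
  if (grepl("ed$", lw) && nchar(w) > 3) return("VBD")
  if (grepl("ing$", lw) && nchar(w) > 4) return("VBG")
  if (grepl("ly$", lw) && nchar(w) > 3) return("RB")
  if (grepl("[^su]s$", lw) && nchar(w) > 3) return("NNS")
  "NN"
}

rule_lemma <- function(w, pos) {
  lw <- w
  if (pos == "NNS") {
    if (grepl("ies$", lw)) return(sub("ies$", "y", lw))
    if (grepl("(ses|xes|ches|shes|zes)$", lw)) return(sub("es$", "", lw))
    return(sub("s$", "", lw))
  }
  if (pos == "VBD" && grepl("ed$", lw)) {
    dropd <- sub("d$", "", lw)
    if (grepl("(ate|ute|ive|ize|ise|ine|ude|ere|use|ose|ace|are)$", dropd))
      return(dropd)
    return(sub("ed$", "", lw))
  }
  if (pos == "VBG" && grepl("ing$", lw)) return(sub("ing$", "", lw))
  lw
}

rule_chunks <- function(pos) {
  np <- c("DT", "JJ", "NN", "NNS", "NNP", "CD", "PRP")
  vb <- c("VBD", "VBZ", "VBP", "VBG", "VB", "VBN")
  out <- character(length(pos))
  prev <- "O"
  for (i in seq_along(pos)) {
    grp <- if (pos[i] %in% np) "NP" else if (pos[i] %in% vb) "VP"
           else if (pos[i] %in% c("IN", "TO")) "PP" else "O"
    out[i] <- if (grp == "O") "O"
              else if (prev == grp && grp != "PP") paste0("I-", grp)
              else paste0("B-", grp)
    prev <- grp
  }
  out
}

#' Deterministic rule-based tagger
#'
#' A dependency-free annotator used when no statistical tagger is plugged in:
#' POS by closed-class lookup and suffix rules, lemmas by plural/inflection
#' stripping, chunks by a regular NP/VP/PP grammar over the POS sequence.
#'
#' @param surfaces Character vector of token surfaces.
#' @return List with character vectors `lemma`, `pos`, `chunk`.
#' @export
fallback_tagger <- function(surfaces) {
  pos <- vapply(surfaces, rule_pos, character(1), USE.NAMES = FALSE)
  lemma <- mapply(rule_lemma, surfaces, pos, USE.NAMES = FALSE)
  list(lemma = as.character(lemma), pos = pos, chunk = rule_chunks(pos))
}

#' Build a tagger that replays fixed annotations
#'
#' Useful for testing and for importing annotations produced by an external
#' tagger: surfaces are looked up in the supplied table; unseen surfaces fall
#' back to [fallback_tagger()].
#'
#' @param table Data frame with columns `surface`, `lemma`, `pos`, `chunk`.
#' @return A tagger function for [tag_tokens()].
#' @export
fixture_tagger <- function(table) {
  force(table)
  function(surfaces) {
    idx <- match(surfaces, table$surface)
    fb <- fallback_tagger(surfaces)
    list(
      lemma = ifelse(is.na(idx), fb$lemma, table$lemma[idx]),
      pos   = ifelse(is.na(idx), fb$pos,   table$pos[idx]),
      chunk = ifelse(is.na(idx), fb$chunk, table$chunk[idx]))
  }
}

#' Preprocess a section: sentences, tokens, annotations
#'
#' @param text Section text.
#' @param splitter `"scientific"` or `"general"`.
#' @param tokeniser `"chemistry"` or `"general"`.
#' @param tagger Tagger function (see [tag_tokens()]).
#' @return List of annotated token data frames, one per sentence, each with
#'   a `sentence_start`/`sentence_end` attribute.
#' @export
preprocess_section <- function(text, splitter = "scientific",
                               tokeniser = "chemistry",
                               tagger = fallback_tagger) {
  sents <- split_sentences(text, splitter)
  out <- vector("list", nrow(sents))
  for (k in seq_len(nrow(sents))) {
    toks <- tag_tokens(tokenise(sents[k, ], tokeniser), tagger)
    attr(toks, "sentence_start") <- sents$start[k]
    attr(toks, "sentence_end") <- sents$end[k]
    out[[k]] <- toks
  }
  out
}
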