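# Chemical basic name segment decomposition.
#
# Systematic and semi-systematic chemical names are built from morpheme-like
# basic name segments ("meth", "oxy", "idine", ...). A token is decomposed by
# first splitting it at letter/digit/punctuation boundaries; each maximal
# letter run is then covered left-to-right by greedy longest matches against
# a segment dictionary, with any residue kept as an unmatched fragment.
# Digit runs are numeric fragments and punctuation runs are delimiters.

#' Load a segment dictionary
#'
#' One lowercase alphabetic segment per line. A small demonstration
#' dictionary ships with the package; production use expects the full
#' Registry File Basic Name Segment Dictionary (3,307 entries) supplied by
#' the user.
#'
#' @param path File path, or `NULL` for the shipped demonstration dictionary.
#' @return Object of class `chem_segdict`.
#' @export
load_segment_dictionary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "segments_demo.txt", package = "chemner")
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x <- x[nzchar(x)]
  if (any(grepl("[^a-z]", x)))
    stop("segment dictionary entries must be lowercase alphabetic: ",
         paste(unique(x[grepl("[^a-z]", x)]), collapse = ", "))
  if (length(x) == 0L) stop("segment dictionary is empty")
  structure(list(set = unique(x), max_len = max(nchar(x))),
            class = "chem_segdict")
}

#' @export
print.chem_segdict <- function(x, ...) {
  cat(sprintf("<chem_segdict: %d segments, longest %d chars>\n",
              length(x$set), x$max_len))
  invisible(x)
}

# Greedily cover one lowercase letter run; returns pieces (text, kind).
cover_letter_run <- function(run, sd) {
  pieces <- list()
  n <- nchar(run)
  i <- 1L
  resid_start <- NA_integer_
  flush_resid <- function(upto) {
    if (!is.na(resid_start))
      pieces[[length(pieces) + 1L]] <<- list(
        text = substr(run, resid_start, upto), kind = "UNMATCHED_FRAGMENT")
    resid_start <<- NA_integer_
  }
  while (i <= n) {
    best <- 0L
    for (len in seq.int(min(sd$max_len, n - i + 1L), 1L)) {
      if (substr(run, i, i + len - 1L) %in% sd$set) { best <- len; break }
    }
    if (best > 0L) {
      flush_resid(i - 1L)
      pieces[[length(pieces) + 1L]] <- list(
        text = substr(run, i, i + best - 1L), kind = "MATCHED")
      i <- i + best
    } else {
      if (is.na(resid_start)) resid_start <- i
      i <- i + 1L
    }
  }
  flush_resid(n)
  pieces
}

#' Decompose a token into basic name segments
#'
#' @param token Non-empty token surface. Matching is case-insensitive (the
#'   token is lower-cased before letter runs are matched), but piece texts
#'   keep the original case.
#' @param sd Segment dictionary from [load_segment_dictionary()].
#' @return Object of class `chem_decomposition`: a data frame with columns
#'   `text` and `kind` (`MATCHED`, `UNMATCHED_FRAGMENT`, `NUMERIC_FRAGMENT`,
#'   `DELIMITER`), whose texts concatenate to the token.
#' @examples
#' sd <- load_segment_dictionary()
#' decompose("10-acetoxyactinidine", sd)
#' @export
decompose <- function(token, sd) {
  if (!nzchar(token)) stop("token must be non-empty")
  cs <- chars(token)
  cls <- ifelse(grepl("[[:alpha:]]", cs), "L",
                ifelse(grepl("[0-9]", cs), "D", "P"))
  runs <- rle(cls)
  pieces <- list()
  pos <- 1L
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    text <- substr(token, pos, pos + len - 1L)
    if (runs$values[r] == "D") {
      pieces[[length(pieces) + 1L]] <- list(text = text,
                                            kind = "NUMERIC_FRAGMENT")
    } else if (runs$values[r] == "P") {
      pieces[[length(pieces) + 1L]] <- list(text = text, kind = "DELIMITER")
    } else {
      sub <- cover_letter_run(tolower(text), sd)
      # restore original casing piece by piece
      off <- 0L
      for (p in sub) {
        p$text <- substr(text, off + 1L, off + nchar(p$text))
        off <- off + nchar(p$text)
        pieces[[length(pieces) + 1L]] <- p
      }
    }
    pos <- pos + len
  }
  out <- data.frame(
    text = vapply(pieces, `[[`, character(1), "text"),
    kind = vapply(pieces, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE)
  class(out) <- c("chem_decomposition", class(out))
  out
}

#' Count basic name segments
#'
#' Matched segments, unmatched letter residues and numeric fragments all
#' count; delimiters (punctuation runs) do not. `10-acetoxyactinidine`
#' therefore has 5 segments (`10`, `acet`, `oxy`, `actin`, `idine`) and
#' `interleukin-2` has 2.
#'
#' @inheritParams decompose
#' @return Non-negative integer.
#' @export
count_segments <- function(token, sd) {
  d <- decompose(token, sd)
  sum(d$kind != "DELIMITER")
}

#' Chemical segment composition ratio
#'
#' The fraction of the token's characters covered by dictionary-matched
#' segments: matched characters over total characters, with digits and
#' punctuation counted in the denominator only. `polycalcium` scores 1.0;
#' `2-methoxyestradiol` scores 16/18 = 0.89; `palytoxin` scores 5/9 = 0.56.
#'
#' @inheritParams decompose
#' @return A real in `[0, 1]`.
#' @export
composition_ratio <- function(token, sd) {
  if (!nzchar(token)) stop("token must be non-empty")
  d <- decompose(token, sd)
  matched <- sum(nchar(d$text[d$kind == "MATCHED"]))
  matched / nchar(token)
}
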