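#' @useDynLib chemner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif
#' @importFrom utils head tail
NULL

MENTION_SUBTYPES <- c("SYSTEMATIC", "TRIVIAL", "FAMILY", "ABBREVIATION",
                      "FORMULA", "IDENTIFIER", "MULTIPLE", "NO_CLASS", "UNTYPED")

#' Construct an empty mention table
#'
#' Mentions are stored as a data frame with one row per mention. Offsets are
#' 0-based, half-open, counted in Unicode code points, and are relative to the
#' section the mention belongs to (`"T"` for title, `"A"` for abstract), which
#' are separate coordinate spaces.
#'
#' @return A zero-row data frame with columns `section`, `start`, `end`,
#'   `text`, `subtype` and `confidence`.
#' @export
empty_mentions <- function() {
  data.frame(section = character(), start = integer(), end = integer(),
             text = character(), subtype = character(),
             confidence = numeric(), stringsAsFactors = FALSE)
}

as_mentions <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(empty_mentions())
  df$section <- as.character(df$section)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$text <- as.character(df$text)
  if (is.null(df$subtype)) df$subtype <- "UNTYPED"
  if (is.null(df$confidence)) df$confidence <- NA_real_
  rownames(df) <- NULL
  df[, c("section", "start", "end", "text", "subtype", "confidence")]
}

#' Create a document
#'
#' A document is the corpus unit: an identifier, a title and an abstract, plus
#' a (possibly empty) table of chemical mentions. Every mention is validated
#' against the section text it points into: its span must lie within the
#' section and the stored surface text must equal the substring at the span.
#'
#' @param doc_id Non-empty document identifier.
#' @param title Title text.
#' @param abstract Abstract text.
#' @param mentions Optional mention data frame (see [empty_mentions()]).
#' @return An object of class `chem_document`.
#' @export
chem_document <- function(doc_id, title = "", abstract = "",
                          mentions = empty_mentions()) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id))
    stop("doc_id must be a non-empty string")
  mentions <- as_mentions(mentions)
  doc <- structure(list(doc_id = doc_id, title = title, abstract = abstract,
                        mentions = mentions),
                   class = "chem_document")
  validate_mentions(doc)
  doc
}

section_text <- function(doc, section) {
  if (identical(section, "T")) doc$title else doc$abstract
}

#' @export
print.chem_document <- function(x, ...) {
  cat(sprintf("<chem_document %s: %d mention(s)>\n", x$doc_id, nrow(x$mentions)))
  cat("  title:    ", x$title, "\n", sep = "")
  cat("  abstract: ", substr(x$abstract, 1, 70),
      if (nchar(x$abstract) > 70) "..." else "", "\n", sep = "")
  invisible(x)
}

validate_mentions <- function(doc) {
  m <- doc$mentions
  if (nrow(m) == 0) return(invisible(doc))
  if (!all(m$section %in% c("T", "A")))
    stop("mention section must be 'T' or 'A'")
  if (any(m$start < 0L | m$start >= m$end))
    stop("mention spans must satisfy 0 <= start < end")
  for (i in seq_len(nrow(m))) {
    txt <- section_text(doc, m$section[i])
    if (m$end[i] > nchar(txt))
      stop(sprintf("doc %s: mention [%d,%d) exceeds section '%s' length %d",
                   doc$doc_id, m$start[i], m$end[i], m$section[i], nchar(txt)))
    found <- substr(txt, m$start[i] + 1L, m$end[i])
    if (!identical(found, m$text[i]))
      stop(sprintf(
        "doc %s: mention text mismatch at %s:[%d,%d): expected '%s', found '%s'",
        doc$doc_id, m$section[i], m$start[i], m$end[i], m$text[i], found))
  }
  invisible(doc)
}

#' Read a CHEMDNER-style abstracts file
#'
#' Each non-empty line carries exactly three tab-separated fields:
#' document id, title, abstract. Files are read as UTF-8.
#'
#' @param path Path to the abstracts TSV.
#' @return A list of [chem_document()] objects with empty mention tables,
#'   in file order.
#' @export
read_abstracts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L)
      stop(sprintf("line %d: expected 3 tab-separated fields, got %d",
                   i, length(fields)))
    docs[[length(docs) + 1L]] <- chem_document(fields[1], fields[2], fields[3])
  }
  docs
}

#' Attach a CHEMDNER-style annotations file to documents
#'
#' Annotation lines carry six tab-separated fields: document id, section
#' (`T` or `A`), start, end, mention text, mention subtype. Offsets are 0-based
#' half-open within the section. Every annotation is checked against the
#' document text: an unknown document id or a span whose substring differs
#' from the text column is an error.
#'
#' @param path Path to the annotations TSV.
#' @param docs A list of documents from [read_abstracts()].
#' @return The documents with mention tables filled in.
#' @export
read_annotations <- function(path, docs) {
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- vector("list", length(docs))
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      stop(sprintf("line %d: expected 6 tab-separated fields, got %d",
                   i, length(f)))
    j <- match(f[1], ids)
    if (is.na(j))
      stop(sprintf("line %d: unknown doc_id '%s'", i, f[1]))
    rows[[j]] <- c(rows[[j]], list(data.frame(
      section = f[2], start = as.integer(f[3]), end = as.integer(f[4]),
      text = f[5], subtype = f[6], confidence = NA_real_,
      stringsAsFactors = FALSE)))
  }
  for (j in seq_along(docs)) {
    if (is.null(rows[[j]])) next
    docs[[j]]$mentions <- as_mentions(do.call(rbind, rows[[j]]))
    validate_mentions(docs[[j]])
  }
  docs
}

#' Write documents to CHEMDNER-style abstracts/annotations files
#'
#' Inverse of [read_abstracts()] and [read_annotations()]; used by the
#' synthetic corpus generator and the command-line tool.
#'
#' @param docs List of documents.
#' @param abstracts_path,annotations_path Output paths (UTF-8, no BOM).
#'   `annotations_path` may be `NULL` to skip mention output.
#' @return Invisibly, `docs`.
#' @export
write_corpus <- function(docs, abstracts_path, annotations_path = NULL) {
  abs_lines <- vapply(docs, function(d)
    paste(d$doc_id, d$title, d$abstract, sep = "\t"), character(1))
  writeLines(abs_lines, abstracts_path, useBytes = FALSE)
  if (!is.null(annotations_path)) {
    ann <- character()
    for (d in docs) {
      m <- d$mentions
      if (nrow(m) == 0) next
      ann <- c(ann, sprintf("%s\t%s\t%d\t%d\t%s\t%s", d$doc_id, m$section,
                            m$start, m$end, m$text, m$subtype))
    }
    writeLines(ann, annotations_path, useBytes = FALSE)
  }
  invisible(docs)
}

order_by_confidence <- function(m) {
  order(-m$confidence, m$section, m$start, m$end)
}

#' Write mention-level (CEM) predictions
#'
#' One line per predicted mention:
#' `doc_id<TAB>S:start:end<TAB>rank<TAB>confidence`, with `S` either `T` or
#' `A`. Ranks are 1-based per document in descending confidence; ties are
#' broken by (section, start, end). Confidences are serialised with six
#' decimal places so output is byte-stable.
#'
#' @param docs List of documents carrying predicted mentions with confidences.
#' @param path Output path.
#' @return Invisibly, the lines written.
#' @export
write_cem_predictions <- function(docs, path) {
  out <- character()
  for (d in docs) {
    m <- d$mentions
    if (nrow(m) == 0) next
    if (any(is.na(m$confidence)))
      stop(sprintf("doc %s: predicted mention without confidence", d$doc_id))
    m <- m[order_by_confidence(m), , drop = FALSE]
    out <- c(out, sprintf("%s\t%s:%d:%d\t%d\t%.6f", d$doc_id, m$section,
                          m$start, m$end, seq_len(nrow(m)), m$confidence))
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(out)
}

#' Read back a CEM prediction file
#'
#' @param path Path written by [write_cem_predictions()].
#' @return Data frame with columns `doc_id`, `section`, `start`, `end`,
#'   `rank`, `confidence`.
#' @export
read_cem_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(doc_id = character(), section = character(),
                      start = integer(), end = integer(), rank = integer(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  loc <- do.call(rbind, strsplit(f[, 2], ":", fixed = TRUE))
  data.frame(doc_id = f[, 1], section = loc[, 1],
             start = as.integer(loc[, 2]), end = as.integer(loc[, 3]),
             rank = as.integer(f[, 3]), confidence = as.numeric(f[, 4]),
             stringsAsFactors = FALSE)
}

#' Write document-indexing (CDI) predictions
#'
#' One line per unique mention string:
#' `doc_id<TAB>text<TAB>rank<TAB>confidence`. Input lists must already be
#' deduplicated and ranked (see [rank_cdi()]).
#'
#' @param cdi Named list: document id -> data frame with columns `text`,
#'   `confidence` in rank order.
#' @param path Output path.
#' @return Invisibly, the lines written.
#' @export
write_cdi_predictions <- function(cdi, path) {
  out <- character()
  for (id in names(cdi)) {
    r <- cdi[[id]]
    if (nrow(r) == 0) next
    out <- c(out, sprintf("%s\t%s\t%d\t%.6f", id, r$text,
                          seq_len(nrow(r)), r$confidence))
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(out)
}

VALID_BIO <- c("O", "B", "I")

check_bio_strings <- function(labels) {
  bad <- setdiff(unique(labels), VALID_BIO)
  if (length(bad))
    stop("invalid BIO label(s): ", paste(bad, collapse = ", "))
  invisible(labels)
}

#' Write sentences in CoNLL column format
#'
#' One token per line with tab-separated columns surface, lemma, POS, chunk
#' and BIO label; a blank line terminates each sentence. [read_conll_bio()]
#' is its exact inverse on those five columns.
#'
#' @param sentences List of token data frames with columns `surface`, `lemma`,
#'   `pos`, `chunk`.
#' @param labels List of character vectors over `{B, I, O}` parallel to
#'   `sentences`.
#' @param path Output path.
#' @return Invisibly, the lines written.
#' @export
write_conll_bio <- function(sentences, labels, path) {
  stopifnot(length(sentences) == length(labels))
  out <- character()
  for (k in seq_along(sentences)) {
    s <- sentences[[k]]
    lab <- labels[[k]]
    check_bio_strings(lab)
    stopifnot(nrow(s) == length(lab))
    out <- c(out, paste(s$surface, s$lemma, s$pos, s$chunk, lab, sep = "\t"), "")
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(out)
}

#' Read a CoNLL BIO column file
#'
#' @param path Path written by [write_conll_bio()].
#' @return List with elements `sentences` (token data frames) and `labels`.
#' @export
read_conll_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  labels <- list()
  cur <- list()
  flush <- function() {
    if (length(cur) == 0) return()
    m <- do.call(rbind, cur)
    sentences[[length(sentences) + 1L]] <<- data.frame(
      surface = m[, 1], lemma = m[, 2], pos = m[, 3], chunk = m[, 4],
      stringsAsFactors = FALSE)
    labels[[length(labels) + 1L]] <<- check_bio_strings(m[, 5])
    cur <<- list()
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L)
      stop("malformed CoNLL line (expected 5 columns): ", ln)
    cur[[length(cur) + 1L]] <- f
  }
  flush()
  list(sentences = sentences, labels = labels)
}
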