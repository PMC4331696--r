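# Mention-level (CEM) and document-indexing (CDI) scoring.
#
# P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), with 0/0 defined as 0.
# Micro averaging pools counts over documents; macro averaging takes the
# mean of per-document metrics, excluding documents with empty gold AND
# empty predictions.

safe_div <- function(a, b) if (b == 0) 0 else a / b

prf <- function(tp, fp, fn) {
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

make_report <- function(tp, fp, fn, scope, mode, per_doc = NULL) {
  if (scope == "micro") {
    m <- prf(tp, fp, fn)
  } else {
    m <- if (length(per_doc)) colMeans(do.call(rbind, per_doc))
         else c(precision = 0, recall = 0, f1 = 0)
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = unname(m["precision"]),
                 recall = unname(m["recall"]), f1 = unname(m["f1"]),
                 scope = scope, mode = mode,
                 n_documents = length(per_doc)),
            class = "chem_eval")
}

#' @export
print.chem_eval <- function(x, ...) {
  cat(sprintf("<%s %s> TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$mode, x$scope, x$tp, x$fp, x$fn,
              x$precision, x$recall, x$f1))
  invisible(x)
}

span_keys <- function(m) paste(m$section, m$start, m$end, sep = ":")

#' Mention-level (CEM) evaluation
#'
#' A predicted mention is a true positive iff its (section, start, end)
#' triple exactly matches a gold mention; matching is type-agnostic.
#'
#' @param gold,pred Lists of documents with gold and predicted mentions;
#'   matched by `doc_id`.
#' @param scope `"micro"` (pooled counts) or `"macro"` (mean of per-document
#'   metrics).
#' @return A `chem_eval` report with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_cem <- function(gold, pred, scope = c("micro", "macro")) {
  scope <- match.arg(scope)
  pid <- vapply(pred, function(d) d$doc_id, character(1))
  tp <- fp <- fn <- 0L
  per_doc <- list()
  for (g in gold) {
    idx <- match(g$doc_id, pid)
    pm <- if (is.na(idx)) empty_mentions() else pred[[idx]]$mentions
    if (anyDuplicated(span_keys(pm)))
      stop(sprintf("doc %s: duplicate identical predictions", g$doc_id))
    gk <- span_keys(g$mentions)
    pk <- span_keys(pm)
    dtp <- sum(pk %in% gk)
    dfp <- sum(!pk %in% gk)
    dfn <- sum(!gk %in% pk)
    tp <- tp + dtp; fp <- fp + dfp; fn <- fn + dfn
    if (dtp + dfp + dfn > 0)
      per_doc[[length(per_doc) + 1L]] <- prf(dtp, dfp, dfn)
  }
  make_report(tp, fp, fn, scope, "CEM", per_doc)
}

#' Document-indexing (CDI) evaluation
#'
#' Per document, predicted unique mention strings are compared with the
#' document's set of unique gold mention strings by exact match.
#'
#' @param gold List of documents with gold mentions.
#' @param pred Named list: `doc_id` -> ranked data frame from [rank_cdi()]
#'   (or a character vector of strings). Lists must be duplicate-free.
#' @inheritParams evaluate_cem
#' @return A `chem_eval` report.
#' @export
evaluate_cdi <- function(gold, pred, scope = c("micro", "macro")) {
  scope <- match.arg(scope)
  tp <- fp <- fn <- 0L
  per_doc <- list()
  for (g in gold) {
    p <- pred[[g$doc_id]]
    ps <- if (is.null(p)) character() else if (is.data.frame(p)) p$text else p
    if (anyDuplicated(ps))
      stop(sprintf("doc %s: duplicate strings in ranked list", g$doc_id))
    gs <- unique(g$mentions$text)
    dtp <- sum(ps %in% gs)
    dfp <- sum(!ps %in% gs)
    dfn <- sum(!gs %in% ps)
    tp <- tp + dtp; fp <- fp + dfp; fn <- fn + dfn
    if (dtp + dfp + dfn > 0)
      per_doc[[length(per_doc) + 1L]] <- prf(dtp, dfp, dfn)
  }
  make_report(tp, fp, fn, scope, "CDI", per_doc)
}

#' False-negative breakdown by mention subtype
#'
#' Gold mentions with no exact-span predicted match, grouped by their
#' subtype, with the share of each subtype among all false negatives.
#'
#' @inheritParams evaluate_cem
#' @return Data frame with columns `subtype`, `count`, `percentage`
#'   (percentage of total FN, rounded to 2 decimal places), sorted by
#'   descending count. Zero rows when there are no false negatives.
#' @export
fn_breakdown <- function(gold, pred) {
  pid <- vapply(pred, function(d) d$doc_id, character(1))
  subtypes <- character()
  for (g in gold) {
    idx <- match(g$doc_id, pid)
    pm <- if (is.na(idx)) empty_mentions() else pred[[idx]]$mentions
    miss <- !span_keys(g$mentions) %in% span_keys(pm)
    subtypes <- c(subtypes, g$mentions$subtype[miss])
  }
  if (length(subtypes) == 0)
    return(data.frame(subtype = character(), count = integer(),
                      percentage = numeric(), stringsAsFactors = FALSE))
  tab <- sort(table(subtypes), decreasing = TRUE)
  data.frame(subtype = names(tab), count = as.integer(tab),
             percentage = round(as.integer(tab) / length(subtypes) * 100, 2),
             stringsAsFactors = FALSE)
}

#' Serialise an evaluation report
#'
#' Writes the report as JSON or TSV, including the macro edge-case
#' convention in the metadata.
#'
#' @param report A `chem_eval` object.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(mode = report$mode, scope = report$scope, tp = report$tp,
           fp = report$fp, fn = report$fn, precision = report$precision,
           recall = report$recall, f1 = report$f1,
           macro_convention = "mean of per-document metrics; documents with empty gold and empty predictions excluded; 0/0 ratios defined as 0"),
      path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    writeLines(c(paste("mode", "scope", "tp", "fp", "fn", "precision",
                       "recall", "f1", sep = "\t"),
                 sprintf("%s\t%s\t%d\t%d\t%d\t%.6f\t%.6f\t%.6f",
                         report$mode, report$scope, report$tp, report$fp,
                         report$fn, report$precision, report$recall,
                         report$f1)), path)
  }
  invisible(path)
}
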