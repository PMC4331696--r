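# Document-level pipeline: preprocess -> features -> CRF -> post-processing.

#' Run configuration
#'
#' The five optimisation dimensions of the recogniser: sentence splitter,
#' tokeniser, knowledge-rich features, abbreviation recognition and
#' composition-based relabelling (the post-processing heuristics require the
#' knowledge-rich feature set, mirroring the experiment design), plus the
#' relabelling thresholds and the seed.
#'
#' @param splitter `"scientific"` or `"general"`.
#' @param tokeniser `"chemistry"` or `"general"`.
#' @param knowledge_rich Use the chemical knowledge-rich features?
#' @param abbrev Enable abbreviation recognition (requires
#'   `knowledge_rich`)?
#' @param composition Enable composition-based relabelling (requires
#'   `knowledge_rich`)?
#' @param t1,t2 Relabelling thresholds (see [relabel_config()]).
#' @param seed Integer seed.
#' @return A `chem_run_config` list.
#' @export
run_config <- function(splitter = c("scientific", "general"),
                       tokeniser = c("chemistry", "general"),
                       knowledge_rich = TRUE, abbrev = FALSE,
                       composition = FALSE, t1 = 0.93, t2 = 0.9,
                       seed = 1L) {
  splitter <- match.arg(splitter)
  tokeniser <- match.arg(tokeniser)
  if ((abbrev || composition) && !knowledge_rich)
    stop("post-processing heuristics require knowledge_rich = TRUE")
  structure(list(splitter = splitter, tokeniser = tokeniser,
                 knowledge_rich = knowledge_rich, abbrev = abbrev,
                 composition = composition, t1 = t1, t2 = t2,
                 seed = as.integer(seed)),
            class = "chem_run_config")
}

feature_schema <- function(cfg, resources) {
  list(splitter = cfg$splitter, tokeniser = cfg$tokeniser,
       knowledge_rich = cfg$knowledge_rich,
       lexicons = vapply(resources$lexicons, function(l) l$name, character(1)))
}

# preprocess both sections of a document
doc_sentences <- function(doc, cfg, tagger = fallback_tagger) {
  out <- list()
  for (section in c("T", "A")) {
    text <- section_text(doc, section)
    if (!nzchar(text)) next
    for (toks in preprocess_section(text, cfg$splitter, cfg$tokeniser,
                                    tagger)) {
      if (nrow(toks) == 0) next
      out[[length(out) + 1L]] <- list(section = section, tokens = toks,
                                      text = text)
    }
  }
  out
}

sentence_features <- function(tokens, resources, cfg) {
  lapply(seq_len(nrow(tokens)), function(i)
    assemble_features(tokens, i, resources, cfg$knowledge_rich))
}

#' Train the recogniser on gold-annotated documents
#'
#' Preprocesses every document under the configuration, encodes gold
#' mentions to BIO labels, assembles feature vectors and fits the CRF.
#'
#' @param docs List of gold documents.
#' @param resources [chem_resources()] bundle.
#' @param cfg [run_config()].
#' @param tagger Pluggable tagger (see [tag_tokens()]).
#' @param lambda,maxit CRF training controls (see [crf_train()]).
#' @return A `chem_crf` model whose stored configuration records the
#'   preprocessing and feature schema.
#' @export
chem_train <- function(docs, resources, cfg = run_config(),
                       tagger = fallback_tagger, lambda = 1.0,
                       maxit = 200L) {
  feats <- list()
  labels <- list()
  for (doc in docs) {
    for (s in doc_sentences(doc, cfg, tagger)) {
      m <- doc$mentions[doc$mentions$section == s$section, , drop = FALSE]
      labels[[length(labels) + 1L]] <- encode_bio(s$tokens, m)
      feats[[length(feats) + 1L]] <- sentence_features(s$tokens, resources,
                                                       cfg)
    }
  }
  crf_train(feats, labels, lambda = lambda, maxit = maxit, seed = cfg$seed,
            config = feature_schema(cfg, resources))
}

#' Annotate documents with predicted chemical mentions
#'
#' Runs the trained CRF over every sentence, applies the enabled
#' post-processing heuristics document-globally, and decodes the final BIO
#' labels to mentions with confidences.
#'
#' @param model `chem_crf` from [chem_train()].
#' @param docs Documents to annotate (gold mentions, if any, are ignored).
#' @inheritParams chem_train
#' @return The documents with predicted mentions; each document also carries
#'   a `cdi` attribute with its ranked unique-mention list from [rank_cdi()].
#' @export
chem_annotate <- function(model, docs, resources, cfg = run_config(),
                          tagger = fallback_tagger) {
  check_schema(model, feature_schema(cfg, resources))
  for (d in seq_along(docs)) {
    doc <- docs[[d]]
    sents <- doc_sentences(doc, cfg, tagger)
    surfaces <- character(); labels <- character(); confs <- numeric()
    lens <- integer(length(sents))
    for (k in seq_along(sents)) {
      pr <- crf_predict(model,
                        sentence_features(sents[[k]]$tokens, resources, cfg))
      surfaces <- c(surfaces, sents[[k]]$tokens$surface)
      labels <- c(labels, pr$labels)
      confs <- c(confs, pr$confidences)
      lens[k] <- nrow(sents[[k]]$tokens)
    }
    if (isTRUE(cfg$abbrev))
      labels <- recognise_abbreviations(surfaces, labels)
    if (isTRUE(cfg$composition))
      labels <- relabel_by_composition(surfaces, labels, confs,
                                       resources$segdict,
                                       relabel_config(cfg$t1, cfg$t2))
    mentions <- empty_mentions()
    pos <- 0L
    for (k in seq_along(sents)) {
      sel <- seq.int(pos + 1L, pos + lens[k])
      pos <- pos + lens[k]
      mentions <- rbind(mentions, decode_mentions(
        labels[sel], confs[sel], sents[[k]]$tokens, sents[[k]]$text,
        sents[[k]]$section))
    }
    doc$mentions <- as_mentions(mentions)
    attr(doc, "cdi") <- rank_cdi(doc$mentions)
    docs[[d]] <- doc
  }
  docs
}

#' Token-level label comparison
#'
#' Utility for measuring token-level recall of chemical tokens (labels `B`
#' or `I`) of a prediction against gold labels; used to quantify the effect
#' of post-processing heuristics.
#'
#' @param gold_labels,pred_labels Parallel BIO vectors (concatenated over
#'   the corpus).
#' @return Named numeric vector with `recall`, `precision`, counts.
#' @export
token_level_stats <- function(gold_labels, pred_labels) {
  stopifnot(length(gold_labels) == length(pred_labels))
  g <- gold_labels != "O"
  p <- pred_labels != "O"
  c(recall = safe_div(sum(g & p), sum(g)),
    precision = safe_div(sum(g & p), sum(p)),
    gold_chemical = sum(g), predicted_chemical = sum(p),
    overlap = sum(g & p))
}
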