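# BIO encoding/decoding and the sequence labeller.
#
# The labeller is a linear-chain conditional random field over {O, B, I}
# with presence-valued string features per token, trained by penalised
# maximum likelihood (L2, L-BFGS-B) and queried for Viterbi label sequences
# and per-token posterior marginals. Transitions O->I and sequence-initial
# I are structurally excluded, so predictions are valid BIO sequences by
# construction.

LABELS <- c("O", "B", "I")

#' Encode gold mentions as BIO labels
#'
#' The first token overlapping a mention is labelled `B`, subsequent
#' overlapping tokens `I`, all others `O`. A gold boundary falling inside a
#' token is expanded to the whole token, with a warning (token splitting
#' would change the feature space).
#'
#' @param tokens Token data frame with `start`/`end` columns in section
#'   coordinates.
#' @param mentions Mention data frame (rows for one section). Overlapping
#'   gold mentions are an error.
#' @return Character vector of BIO labels, one per token.
#' @export
encode_bio <- function(tokens, mentions) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  if (is.null(mentions) || nrow(mentions) == 0) return(labels)
  m <- mentions[order(mentions$start), , drop = FALSE]
  if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)]))
    stop("overlapping gold mentions")
  for (r in seq_len(nrow(m))) {
    ov <- which(tokens$start < m$end[r] & m$start[r] < tokens$end)
    if (length(ov) == 0) next
    if (m$start[r] > tokens$start[ov[1]] ||
        m$end[r] < tokens$end[ov[length(ov)]])
      warning(sprintf(
        "mention [%d,%d) does not align with token boundaries; expanded",
        m$start[r], m$end[r]))
    if (any(labels[ov] != "O")) stop("overlapping gold mentions")
    labels[ov[1]] <- "B"
    if (length(ov) > 1) labels[ov[-1]] <- "I"
  }
  labels
}

check_bio_valid <- function(labels) {
  if (length(labels) == 0) return(invisible(labels))
  check_bio_strings(labels)
  prev <- c("O", head(labels, -1))
  if (labels[1] == "I" || any(labels == "I" & prev == "O"))
    stop("invalid BIO sequence: 'I' not preceded by 'B' or 'I'")
  invisible(labels)
}

fingerprint_string <- function(x) {
  codes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 0
  for (chunk in split(codes, ceiling(seq_along(codes) / 4096)))
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Train the CRF sequence labeller
#'
#' Penalised maximum-likelihood training of a linear-chain CRF on assembled
#' feature vectors, deterministic for a fixed seed and input order.
#'
#' @param features List of sentences; each sentence a list of per-token
#'   character vectors of feature strings (see [assemble_features()]).
#' @param labels List of BIO label vectors parallel to `features`; at least
#'   one sentence must contain a `B`.
#' @param lambda L2 regularisation strength (default 1).
#' @param maxit Maximum L-BFGS-B iterations.
#' @param seed Integer seed recorded in the model metadata (training itself
#'   is deterministic: weights start at zero).
#' @param config Arbitrary feature-configuration list stored and
#'   fingerprinted with the model; predictions check it.
#' @return Object of class `chem_crf`.
#' @export
crf_train <- function(features, labels, lambda = 1.0, maxit = 200L,
                      seed = 1L, config = list()) {
  if (length(features) == 0L) stop("empty training corpus")
  stopifnot(length(features) == length(labels))
  for (l in labels) check_bio_valid(l)
  if (!any(vapply(labels, function(l) any(l == "B"), logical(1))))
    stop("training corpus contains no entity (all-O labels)")
  vocab <- sort(unique(unlist(features, use.names = FALSE)))
  nfeat <- length(vocab)
  fsent <- lapply(features, function(s)
    lapply(s, function(f) match(f, vocab)))
  lsent <- lapply(labels, function(l) match(l, LABELS))
  npar <- nfeat * 3L + 9L
  cache <- new.env(parent = emptyenv())
  eval_at <- function(w) {
    if (is.null(cache$w) || !identical(cache$w, w)) {
      cache$r <- .crf_nll_grad(w, fsent, lsent, nfeat)
      cache$w <- w
    }
    cache$r
  }
  obj <- function(w) eval_at(w)$nll + 0.5 * lambda * sum(w^2)
  grd <- function(w) eval_at(w)$grad + lambda * w
  fit <- stats::optim(rep(0, npar), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  cfg_fp <- fingerprint_string(c(
    vapply(seq_along(config), function(i)
      paste0(names(config)[i], "=", paste(config[[i]], collapse = ",")),
      character(1)),
    sprintf("nfeat=%d", nfeat)))
  structure(list(weights = fit$par, vocab = vocab, labels = LABELS,
                 lambda = lambda, seed = as.integer(seed), config = config,
                 fingerprint = cfg_fp, value = fit$value,
                 convergence = fit$convergence),
            class = "chem_crf")
}

#' @export
print.chem_crf <- function(x, ...) {
  cat(sprintf("<chem_crf: %d features, lambda = %g, fingerprint %s>\n",
              length(x$vocab), x$lambda, x$fingerprint))
  invisible(x)
}

sentence_indices <- function(model, sent_features) {
  lapply(sent_features, function(f) {
    idx <- match(f, model$vocab)
    idx[!is.na(idx)]
  })
}

check_schema <- function(model, config) {
  if (!is.null(config) && !identical(model$config, config))
    stop("feature schema mismatch: model was trained under a different ",
         "feature configuration")
}

#' Predict a BIO label sequence with marginal confidences
#'
#' Viterbi decoding plus forward-backward posteriors: the confidence of each
#' token is the marginal probability of its assigned label, so per-token
#' marginals over `{B, I, O}` sum to one.
#'
#' @param model A [crf_train()] model.
#' @param sent_features One sentence: list of per-token feature-string
#'   vectors. Features unseen in training are ignored.
#' @param config If supplied, checked against the model's stored feature
#'   configuration; a mismatch is an error.
#' @return List with `labels` (BIO character vector) and `confidences`
#'   (numeric vector in `[0, 1]`).
#' @export
crf_predict <- function(model, sent_features, config = NULL) {
  check_schema(model, config)
  idx <- sentence_indices(model, sent_features)
  nfeat <- length(model$vocab)
  y <- .crf_viterbi(model$weights, idx, nfeat)
  marg <- .crf_marginals(model$weights, idx, nfeat)
  conf <- if (length(y)) marg[cbind(seq_along(y), y)] else numeric()
  labels <- LABELS[y]
  check_bio_valid(labels)
  list(labels = labels, confidences = conf)
}

#' Full per-token marginal table
#'
#' @inheritParams crf_predict
#' @return Numeric matrix with one row per token and columns `O`, `B`, `I`;
#'   each row sums to one.
#' @export
crf_marginal_table <- function(model, sent_features) {
  idx <- sentence_indices(model, sent_features)
  m <- .crf_marginals(model$weights, idx, length(model$vocab))
  colnames(m) <- LABELS
  m
}

#' Decode BIO labels back to mentions
#'
#' Each maximal `B I*` run becomes a mention spanning the first token's start
#' to the last token's end. The mention confidence is the minimum of its
#' member tokens' confidences (a conservative score for CDI ranking).
#'
#' @param labels Valid BIO label vector.
#' @param confidences Per-token confidences parallel to `labels` (optional).
#' @param tokens Token data frame with `start`/`end` in section coordinates.
#' @param text Section text (for the mention surface).
#' @param section `"T"` or `"A"`.
#' @return Mention data frame (see [empty_mentions()]).
#' @export
decode_mentions <- function(labels, confidences = NULL, tokens, text,
                            section = "A") {
  check_bio_valid(labels)
  if (is.null(confidences)) confidences <- rep(NA_real_, length(labels))
  out <- empty_mentions()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] == "B") {
      j <- i
      while (j < n && labels[j + 1L] == "I") j <- j + 1L
      s <- tokens$start[i]; e <- tokens$end[j]
      out <- rbind(out, data.frame(
        section = section, start = s, end = e,
        text = substr(text, s + 1L, e), subtype = "UNTYPED",
        confidence = suppressWarnings(min(confidences[i:j])),
        stringsAsFactors = FALSE))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Save / load a trained model
#'
#' The model is serialised to `path`; a JSON sidecar `<path>.meta.json`
#' records the feature-configuration fingerprint, regularisation, seed and
#' feature count for reproducibility audits.
#'
#' @param model A `chem_crf` model.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_crf_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(fingerprint = model$fingerprint, lambda = model$lambda,
               seed = model$seed, n_features = length(model$vocab),
               config = model$config)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_crf_model
#' @export
load_crf_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "chem_crf")) stop("not a chem_crf model file")
  model
}
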