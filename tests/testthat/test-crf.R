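toy_tokens <- function(n, width = 3L) {
  data.frame(surface = replicate(n, paste(sample(letters, width),
                                          collapse = "")),
             start = seq(0L, by = width + 1L, length.out = n),
             end = seq(0L, by = width + 1L, length.out = n) + width,
             stringsAsFactors = FALSE)
}

test_that("gold mentions encode to BIO with boundary handling", {
  toks <- toy_tokens(6)
  m <- data.frame(section = "A", start = toks$start[4], end = toks$end[5],
                  text = "x", subtype = "UNTYPED", confidence = NA_real_)
  expect_equal(encode_bio(toks, m), c("O", "O", "O", "B", "I", "O"))
  expect_equal(encode_bio(toks, NULL), rep("O", 6))

  # boundary inside a token: whole token labelled, warning raised
  m2 <- data.frame(section = "A", start = toks$start[4] + 1L,
                   end = toks$end[4], text = "x", subtype = "UNTYPED",
                   confidence = NA_real_)
  expect_warning(lab <- encode_bio(toks, m2), "expanded")
  expect_equal(lab[4], "B")

  m3 <- rbind(m, data.frame(section = "A", start = toks$start[5],
                            end = toks$end[6], text = "y",
                            subtype = "UNTYPED", confidence = NA_real_))
  expect_error(encode_bio(toks, m3), "overlapping")
})

test_that("decoding inverts encoding for token-aligned mentions", {
  set.seed(5)
  for (trial in 1:50) {
    n <- sample(2:9, 1)
    toks <- toy_tokens(n)
    text <- paste(rep("x", max(toks$end)), collapse = "")
    labels <- random_bio(n)
    men <- decode_mentions(labels, rep(0.5, n), toks, text, "A")
    expect_equal(encode_bio(toks, men), labels)
  }
  # adjacent single-token mentions stay separate
  toks <- toy_tokens(2)
  men <- decode_mentions(c("B", "B"), c(0.9, 0.8), toks,
                         paste(rep("x", 10), collapse = ""), "A")
  expect_equal(nrow(men), 2)
  expect_error(decode_mentions(c("I", "O"), NULL, toks, "xxxx", "A"),
               "invalid BIO")
})

make_toy_corpus <- function(n_sent, seed) {
  set.seed(seed)
  feats <- list(); labels <- list()
  for (s in seq_len(n_sent)) {
    n <- sample(3:7, 1)
    lab <- rep("O", n)
    i <- sample(n, 1)
    lab[i] <- "B"
    if (i < n && runif(1) < 0.5) lab[i + 1] <- "I"
    fs <- lapply(seq_len(n), function(t) {
      base <- if (lab[t] == "O") sample(c("w=the", "w=of", "w=cat"), 2)
              else sample(c("w=acid", "w=oxide", "chr2=yl"), 2)
      c(base, sprintf("pos=%d", t %% 3))
    })
    feats[[s]] <- fs
    labels[[s]] <- lab
  }
  list(features = feats, labels = labels)
}

test_that("training is deterministic and rejects degenerate corpora", {
  tc <- make_toy_corpus(25, 42)
  m1 <- crf_train(tc$features, tc$labels, maxit = 60)
  m2 <- crf_train(tc$features, tc$labels, maxit = 60)
  p1 <- lapply(tc$features, function(s) crf_predict(m1, s))
  p2 <- lapply(tc$features, function(s) crf_predict(m2, s))
  expect_identical(p1, p2)

  expect_error(crf_train(list(), list()), "empty")
  allo <- list(list(c("w=a"), c("w=b")))
  expect_error(crf_train(allo, list(c("O", "O"))), "all-O")
})

test_that("predictions are valid BIO with calibrated marginals", {
  tc <- make_toy_corpus(40, 7)
  model <- crf_train(tc$features, tc$labels, maxit = 80)
  for (s in tc$features[1:10]) {
    pr <- crf_predict(model, s)
    expect_true(all(pr$confidences >= 0 & pr$confidences <= 1))
    expect_silent(chemner:::check_bio_valid(pr$labels))
    marg <- crf_marginal_table(model, s)
    expect_equal(unname(rowSums(marg)), rep(1, length(s)), tolerance = 1e-6)
    # confidence of the assigned label equals its marginal
    expect_equal(pr$confidences,
                 marg[cbind(seq_along(pr$labels),
                            match(pr$labels, c("O", "B", "I")))])
  }
  # BIO validity is structural: surviving even under heavy regularisation
  heavy <- crf_train(tc$features, tc$labels, lambda = 100, maxit = 40)
  for (s in tc$features[1:5])
    expect_silent(chemner:::check_bio_valid(crf_predict(heavy, s)$labels))
})

test_that("the model memorises separable data and round-trips via disk", {
  tc <- make_toy_corpus(60, 11)
  model <- crf_train(tc$features, tc$labels, maxit = 100)
  correct <- 0L; total <- 0L
  tp <- fp <- fn <- 0L
  for (s in seq_along(tc$features)) {
    pr <- crf_predict(model, tc$features[[s]])
    g <- tc$labels[[s]] != "O"; p <- pr$labels != "O"
    tp <- tp + sum(g & p); fp <- fp + sum(!g & p); fn <- fn + sum(g & !p)
  }
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.95)

  path <- withr::local_tempfile()
  save_crf_model(model, path)
  back <- load_crf_model(path)
  expect_identical(back$weights, model$weights)
  expect_true(file.exists(paste0(path, ".meta.json")))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$fingerprint, model$fingerprint)

  # schema mismatch is an error
  m2 <- crf_train(tc$features, tc$labels, maxit = 10,
                  config = list(knowledge_rich = TRUE))
  expect_error(crf_predict(m2, tc$features[[1]],
                           config = list(knowledge_rich = FALSE)),
               "schema mismatch")
})
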