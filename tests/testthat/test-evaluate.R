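doc_with <- function(id, spans, subtypes = NULL, n = 60L, conf = 0.9) {
  text <- paste(rep("x", n), collapse = "")
  if (length(spans)) {
    m <- do.call(rbind, lapply(spans, function(s)
      data.frame(section = "A", start = s[1], end = s[2],
                 text = substr(text, s[1] + 1, s[2]),
                 stringsAsFactors = FALSE)))
    m$subtype <- if (is.null(subtypes)) "UNTYPED" else subtypes
    m$confidence <- conf
  } else m <- empty_mentions()
  chem_document(id, "t", text, m)
}

test_that("mention-level scoring follows the P/R/F1 definitions", {
  gold <- list(doc_with("D1", list(c(0, 3), c(5, 8), c(10, 13), c(15, 18))))
  pred <- list(doc_with("D1", list(c(0, 3), c(5, 8), c(20, 23))))
  # tp=2, fp=1, fn=2
  r <- evaluate_cem(gold, pred, "micro")
  expect_equal(c(r$tp, r$fp, r$fn), c(2, 1, 2))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 1 / 2)
  expect_equal(r$f1, 4 / 7)

  same <- evaluate_cem(gold, gold, "micro")
  expect_equal(c(same$precision, same$recall, same$f1), c(1, 1, 1))

  none <- evaluate_cem(gold, list(doc_with("D1", list())), "micro")
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))

  dup <- list(doc_with("D1", list(c(0, 3), c(0, 3))))
  expect_error(evaluate_cem(gold, dup, "micro"), "duplicate")
})

test_that("document-indexing scoring matches on unique strings", {
  gold <- list(chem_document("D1", "t", "aspirin and NO2 here",
    data.frame(section = "A", start = c(0L, 12L), end = c(7L, 15L),
               text = c("aspirin", "NO2"))))
  r <- evaluate_cdi(gold, list(D1 = "aspirin"), "micro")
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 / 3)

  sup <- evaluate_cdi(gold, list(D1 = c("aspirin", "NO2", "zzz")), "micro")
  expect_equal(sup$recall, 1)
  expect_lt(sup$precision, 1)

  expect_error(evaluate_cdi(gold, list(D1 = c("aspirin", "aspirin"))),
               "duplicate")

  both_empty <- evaluate_cdi(list(chem_document("D2", "t", "nothing")),
                             list(D2 = character()), "macro")
  expect_equal(both_empty$n_documents, 0)  # excluded from the macro mean
})

test_that("micro is partition-invariant; macro is not", {
  # one document split into two: micro counts pool identically
  g_one <- list(doc_with("D1", list(c(0, 3), c(5, 8))))
  p_one <- list(doc_with("D1", list(c(0, 3), c(5, 8), c(20, 23))))
  g_two <- list(doc_with("D1", list(c(0, 3))),
                doc_with("D2", list(c(5, 8))))
  p_two <- list(doc_with("D1", list(c(0, 3))),
                doc_with("D2", list(c(5, 8), c(20, 23))))
  m1 <- evaluate_cem(g_one, p_one, "micro")
  m2 <- evaluate_cem(g_two, p_two, "micro")
  expect_equal(c(m1$precision, m1$recall, m1$f1),
               c(m2$precision, m2$recall, m2$f1))
  M1 <- evaluate_cem(g_one, p_one, "macro")
  M2 <- evaluate_cem(g_two, p_two, "macro")
  expect_false(isTRUE(all.equal(M1$f1, M2$f1)))
})

test_that("F1 sits between precision and recall (harmonic mean)", {
  set.seed(17)
  for (trial in 1:100) {
    tp <- sample(0:10, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    gold <- list(doc_with("D1", lapply(seq_len(tp + fn) - 1,
                                       function(i) c(i * 4, i * 4 + 2)),
                          n = 200L))
    pred_spans <- c(lapply(seq_len(tp) - 1, function(i) c(i * 4, i * 4 + 2)),
                    lapply(seq_len(fp), function(i) c(100 + i * 4, 102 + i * 4)))
    pred <- list(doc_with("D1", pred_spans, n = 200L))
    r <- evaluate_cem(gold, pred, "micro")
    expect_equal(c(r$tp, r$fp, r$fn), c(tp, fp, fn))
    if (r$precision > 0 && r$recall > 0) {
      expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
      expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
    }
  }
})

test_that("false-negative breakdown reproduces the published distribution", {
  freqs <- c(Abbreviation = 1882, Formula = 1291, Family = 979,
             Trivial = 926, Systematic = 693, Identifier = 293,
             Multiple = 118, `No class` = 25)
  spans <- lapply(seq_len(sum(freqs)) - 1, function(i) c(i, i + 1))
  gold <- list(doc_with("D1", spans, subtypes = rep(names(freqs), freqs),
                        n = sum(freqs) + 1L))
  bd <- fn_breakdown(gold, list(doc_with("D1", list(),
                                         n = sum(freqs) + 1L)))
  expect_equal(bd$percentage[bd$subtype == "Abbreviation"], 30.32)
  expect_equal(bd$percentage[bd$subtype == "Formula"], 20.80)
  expect_equal(sum(bd$count), sum(freqs))
  expect_lt(abs(sum(bd$percentage) - 100), 0.05)

  single <- fn_breakdown(list(doc_with("D1", list(c(0, 2)), "TRIVIAL")),
                         list(doc_with("D1", list())))
  expect_equal(single$percentage, 100.00)

  none <- fn_breakdown(gold, gold)
  expect_equal(nrow(none), 0)
})
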