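test_that("abbreviation verification scans characters in order", {
  expect_true(verify_abbreviation("STMP", "sodium trimetaphosphate"))
  expect_false(verify_abbreviation("XYZ", "glucose"))
  expect_true(verify_abbreviation(
    "HES-HEMA", "hydroxyethyl starch-hydroxyethyl methacrylate"))
  # oracle: independent subsequence check via regex
  set.seed(13)
  for (trial in 1:200) {
    cand <- paste(sample(letters[1:6], sample(1:4, 1), replace = TRUE),
                  collapse = "")
    ent <- paste(sample(letters[1:6], sample(2:12, 1), replace = TRUE),
                 collapse = "")
    want <- grepl(paste(strsplit(cand, "")[[1]], collapse = ".*"), ent)
    expect_equal(verify_abbreviation(cand, ent), want)
  }
})

abbrev_fixture <- function() {
  surf <- c("was", "phosphorylated", "with", "sodium", "trimetaphosphate",
            "(", "STMP", ")", "at", "ambient", "temperature", ".",
            "Then", "STMP", "was", "added", ".")
  lab <- rep("O", length(surf))
  lab[4] <- "B"; lab[5] <- "I"
  list(surfaces = surf, labels = lab)
}

test_that("recognised abbreviations are captured document-wide", {
  fx <- abbrev_fixture()
  out <- recognise_abbreviations(fx$surfaces, fx$labels)
  stmp <- fx$surfaces == "STMP"
  expect_true(all(out[stmp] == "B"))
  # no token with the captured surface stays O; nothing is removed
  expect_true(all(out[fx$labels != "O"] != "O"))

  # missing closing parenthesis: unchanged
  fx2 <- fx
  fx2$surfaces[8] <- "x"
  expect_equal(recognise_abbreviations(fx2$surfaces, fx2$labels), fx2$labels)

  # candidate already chemical: condition requires non-chemical
  fx3 <- fx
  fx3$labels[7] <- "B"
  expect_equal(recognise_abbreviations(fx3$surfaces, fx3$labels), fx3$labels)

  # failed subsequence verification: unchanged
  fx4 <- fx
  fx4$surfaces[7] <- "XYZQ"
  fx4$surfaces[14] <- "XYZQ"
  expect_equal(recognise_abbreviations(fx4$surfaces, fx4$labels), fx4$labels)
})

test_that("composition relabelling honours both strict thresholds", {
  sdict <- load_segment_dictionary()
  cfg <- relabel_config()  # t1 = 0.93, t2 = 0.9
  surf <- c("polycalcium", "palytoxin", "polycalcium")
  lab <- c("O", "O", "O")
  out <- relabel_by_composition(surf, lab, c(0.90, 0.90, 0.99), sdict, cfg)
  expect_equal(out, c("B", "O", "O"))  # high-confidence O untouched
  # ratio exactly at t2 is not relabelled (strictly greater required)
  out2 <- relabel_by_composition("methoxy", "O", 0.5, sdict,
                                 relabel_config(t2 = 1.0))
  expect_equal(out2, "O")
  # confidence exactly at t1 is not a candidate (strictly lower required)
  out3 <- relabel_by_composition("polycalcium", "O", 0.93, sdict, cfg)
  expect_equal(out3, "O")
  # B/I labels are never touched
  out4 <- relabel_by_composition(surf, c("B", "I", "O"), c(0, 0, 0), sdict,
                                 cfg)
  expect_equal(out4[1:2], c("B", "I"))
})

test_that("post-processing is monotone on the chemical token set", {
  sdict <- load_segment_dictionary()
  set.seed(21)
  vocab <- c("polycalcium", "palytoxin", "the", "STMP", "(", ")", "rats")
  for (trial in 1:100) {
    n <- sample(4:12, 1)
    surf <- sample(vocab, n, replace = TRUE)
    lab <- random_bio(n)
    conf <- runif(n)
    before <- lab != "O"
    l1 <- recognise_abbreviations(surf, lab)
    l2 <- relabel_by_composition(surf, l1, conf, sdict, relabel_config())
    expect_true(all(before <= (l2 != "O")))
  }
})

test_that("CDI ranking dedupes by max confidence with stable ties", {
  m <- data.frame(section = "A", start = c(0L, 5L, 10L),
                  end = c(3L, 8L, 13L),
                  text = c("aspirin", "aspirin", "NO2"),
                  subtype = "UNTYPED", confidence = c(0.9, 0.7, 0.8),
                  stringsAsFactors = FALSE)
  r <- rank_cdi(m)
  expect_equal(r$text, c("aspirin", "NO2"))
  expect_equal(r$confidence, c(0.9, 0.8))
  expect_equal(nrow(rank_cdi(empty_mentions())), 0)
  # brute-force oracle
  set.seed(31)
  for (trial in 1:100) {
    k <- sample(1:6, 1)
    mm <- data.frame(section = "A", start = 0L, end = 1L,
                     text = sample(c("a", "b", "c"), k, replace = TRUE),
                     subtype = "UNTYPED",
                     confidence = round(runif(k), 2),
                     stringsAsFactors = FALSE)
    r <- rank_cdi(mm)
    agg <- tapply(mm$confidence, mm$text, max)
    want <- data.frame(text = names(agg), confidence = as.numeric(agg),
                       stringsAsFactors = FALSE)
    want <- want[order(-want$confidence, want$text), ]
    expect_equal(r$text, want$text)
    expect_equal(r$confidence, want$confidence)
  }
})
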