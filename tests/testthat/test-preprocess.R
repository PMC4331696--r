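test_that("scientific splitter accepts lowercase sentence starts", {
  expect_equal(nrow(split_sentences(
    "It attenuated GSK214a-induced gestation in rats.", "scientific")), 1)
  expect_equal(nrow(split_sentences("", "scientific")), 0)

  sci <- split_sentences("X was low. p53 rose.", "scientific")
  gen <- split_sentences("X was low. p53 rose.", "general")
  expect_equal(sci$text, c("X was low.", "p53 rose."))
  expect_equal(gen$text, "X was low. p53 rose.")

  # abbreviation exceptions never split
  one <- split_sentences("Seen in mice, e.g. rats and voles.", "scientific")
  expect_equal(nrow(one), 1)
})

test_that("sentence spans cover all non-whitespace with exact offsets", {
  txt <- "First one here.  Second p53 sentence! Third."
  sp <- split_sentences(txt, "scientific")
  for (k in seq_len(nrow(sp)))
    expect_equal(substr(txt, sp$start[k] + 1, sp$end[k]), sp$text[k])
  covered <- unlist(lapply(seq_len(nrow(sp)),
                           function(k) seq(sp$start[k] + 1, sp$end[k])))
  nonws <- which(strsplit(txt, "")[[1]] != " ")
  expect_true(all(nonws %in% covered))
})

test_that("chemistry tokeniser keeps systematic names intact", {
  tk <- function(text) tokenise(data.frame(text = text, start = 0L,
                                           stringsAsFactors = FALSE))$surface
  expect_equal(tk("4,9-Diazadodecane-1,12-diamine"),
               "4,9-Diazadodecane-1,12-diamine")
  expect_equal(tk("GSK214a-induced gestation"),
               c("GSK214a", "-induced", "gestation"))
  expect_equal(tk("rats."), c("rats", "."))
  expect_equal(tk("trimetaphosphate (STMP) at"),
               c("trimetaphosphate", "(", "STMP", ")", "at"))
  # balanced internal brackets survive; wrapping ones split off
  expect_equal(tk("bis-(4-nitrophenyl)"), "bis-(4-nitrophenyl)")
  expect_equal(tk("(E/Z)-Goniothalamin"), "(E/Z)-Goniothalamin")
})

test_that("general tokeniser splits at all punctuation", {
  toks <- tokenise(data.frame(text = "4,9-diamine.", start = 0L), "general")
  expect_equal(toks$surface, c("4", ",", "9", "-", "diamine", "."))
})

test_that("token offsets reconstruct the sentence exactly", {
  texts <- c("It attenuated GSK214a-induced gestation in rats.",
             "Treatment with bis-(4-nitrophenyl) phosphate (BNPP) works.",
             "A 4,9-Diazadodecane-1,12-diamine level of 85% was seen; fine.")
  for (text in texts) {
    for (mode in c("chemistry", "general")) {
      toks <- tokenise(data.frame(text = text, start = 0L), mode)
      expect_true(all(diff(toks$start) > 0))
      expect_true(all(toks$end > toks$start))
      expect_true(all(toks$start[-1] >= head(toks$end, -1)))
      for (i in seq_len(nrow(toks)))
        expect_equal(substr(text, toks$start[i] + 1, toks$end[i]),
                     toks$surface[i])
      # re-assembling surfaces with original gaps reproduces the text
      rebuilt <- ""
      pos <- 0L
      for (i in seq_len(nrow(toks))) {
        rebuilt <- paste0(rebuilt,
                          substr(text, pos + 1, toks$start[i]),
                          toks$surface[i])
        pos <- toks$end[i]
      }
      rebuilt <- paste0(rebuilt, substr(text, pos + 1, nchar(text)))
      expect_identical(rebuilt, text)
    }
  }
})

test_that("tokenisation is idempotent on single-token texts", {
  singles <- c("4,9-Diazadodecane-1,12-diamine", "-induced", "(", ".",
               "GSK214a", "bis-(4-nitrophenyl)")
  for (s in singles) {
    once <- tokenise(data.frame(text = s, start = 0L))
    if (nrow(once) == 1) {
      again <- tokenise(data.frame(text = once$surface, start = 0L))
      expect_equal(again$surface, once$surface)
    }
  }
})

test_that("the fixture tagger replays the annotated example sentence", {
  toks <- table8_tokens()
  ref <- table8_annotations()
  expect_equal(toks$surface, ref$surface)
  expect_equal(toks$lemma, ref$lemma)
  expect_equal(toks$pos, ref$pos)
  expect_equal(toks$chunk, ref$chunk)
})

test_that("the fallback tagger applies its suffix and plural rules", {
  out <- fallback_tagger(c("rats", "attenuated"))
  expect_equal(out$lemma[1], "rat")
  expect_equal(out$pos[2], "VBD")
  expect_error(
    tag_tokens(data.frame(surface = c("a", "b"), start = 0:1, end = 1:2),
               function(s) list(lemma = "x", pos = "NN", chunk = "O")),
    "1 'lemma' annotations for 2 tokens")
})
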