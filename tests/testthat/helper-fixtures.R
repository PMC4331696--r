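# Shared fixtures: the annotated example sentence, the CTD-like dictionary
# excerpt and a resource bundle. Everything is built in code.

table8_annotations <- function() {
  data.frame(
    surface = c("It", "attenuated", "GSK214a", "-induced", "gestation",
                "in", "rats", "."),
    lemma = c("It", "attenuate", "GSK214a", "-induced", "gestation",
              "in", "rat", "."),
    pos = c("PRP", "VBD", "NN", "JJ", "NN", "IN", "NN", "."),
    chunk = c("B-NP", "B-VP", "B-NP", "I-NP", "I-NP", "B-PP", "B-NP", "O"),
    stringsAsFactors = FALSE)
}

table8_tokens <- function() {
  text <- "It attenuated GSK214a-induced gestation in rats."
  sent <- split_sentences(text, "scientific")
  tag_tokens(tokenise(sent[1, ], "chemistry"),
             fixture_tagger(table8_annotations()))
}

ctd_lexicon <- function() {
  compile_lexicon(c("hydrogel", "hydroxyethyl starch",
                    "hydroxyethyl methacrylate"), name = "CTD")
}

table10_surfaces <- function() {
  c("For", "the", "preparation", "of", "hydrogel", "microspheres", "based",
    "on", "hydroxyethyl", "starch", "-", "hydroxyethyl", "methacrylate",
    "(", "HES-HEMA", ")")
}

table10_lemmas <- function() {
  c("for", "the", "preparation", "of", "hydrogel", "microsphere", "base",
    "on", "hydroxyethyl", "starch", "-", "hydroxyethyl", "methacrylate",
    "(", "hes-hema", ")")
}

demo_resources <- function() {
  chem_resources(lexicons = list(compile_lexicon(
    system.file("extdata", "lexicon_demo.txt", package = "chemner"),
    name = "DEMO", from_file = TRUE)))
}

# concatenated gold/predicted BIO labels over a document list, under cfg
corpus_bio_labels <- function(docs, cfg) {
  unlist(lapply(docs, function(d) {
    unlist(lapply(chemner:::doc_sentences(d, cfg), function(s)
      encode_bio(s$tokens, d$mentions[d$mentions$section == s$section, ,
                                      drop = FALSE])))
  }))
}

random_bio <- function(n) {
  labels <- character(n)
  prev <- "O"
  for (i in seq_len(n)) {
    labels[i] <- if (prev == "O") sample(c("O", "B"), 1)
                 else sample(c("O", "B", "I"), 1)
    prev <- labels[i]
  }
  labels
}
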