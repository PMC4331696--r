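# Seed-reproducible synthetic corpus generator.
#
# Stands in for hand-annotated training data at desk scale: documents are
# built from sentence templates with embedded chemical-like names whose
# letter material is drawn from the shipped basic-segment dictionary and
# affix lists, so the knowledge-rich features are informative by
# construction. Gold mention offsets are exact by construction. The
# generator makes no claim of statistical fidelity to real corpora; it
# produces regular, separable data for pipeline validation.

NAME_TEMPLATES <- c(
  "It attenuated {N}-induced gestation in rats.",
  "We tested {N} in a cohort of patients.",
  "Treatment with {N} reduced the symptoms.",
  "The effects of {N} were dose dependent.",
  "Exposure to {N} increased enzyme activity.",
  "Oral administration of {N} was well tolerated.")

ABBREV_TEMPLATE <- "Samples were treated with {N} ({A}) overnight."
ABBREV_USE_TEMPLATE <- "Higher doses of {A} were toxic."

TITLE_TEMPLATES <- c("Effects of {N} in experimental models.",
                     "A study of {N} toxicity.")
TITLE_PLAIN <- c("A controlled laboratory study.",
                 "Observations from a clinical series.")

DISTRACTOR_SENTENCES <- c(
  "The patients recovered quickly.",
  "Samples were stored at ambient temperature.",
  "No adverse events were observed during the study.",
  "The experimental protocol was approved by the committee.",
  "Results were consistent across replicates.")

#' Synthetic corpus configuration
#'
#' @param n_documents Number of documents (>= 1).
#' @param names_per_doc Integer range (length 2) of chemical-name sentences
#'   per document.
#' @param abbreviation_rate Probability that a document introduces a
#'   parenthesised abbreviation for one of its names and re-uses it later.
#' @param distractor_rate Probability of inserting a chemical-free
#'   distractor sentence after each content sentence.
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return A `chem_synth_config` list.
#' @export
synth_config <- function(n_documents = 10L, names_per_doc = c(2L, 4L),
                         abbreviation_rate = 0.3, distractor_rate = 0.5,
                         seed = 1L) {
  stopifnot(n_documents >= 1,
            length(names_per_doc) == 2, names_per_doc[1] >= 1,
            names_per_doc[2] >= names_per_doc[1],
            abbreviation_rate >= 0, abbreviation_rate <= 1,
            distractor_rate >= 0, distractor_rate <= 1)
  structure(list(n_documents = as.integer(n_documents),
                 names_per_doc = as.integer(names_per_doc),
                 abbreviation_rate = abbreviation_rate,
                 distractor_rate = distractor_rate,
                 seed = as.integer(seed)),
            class = "chem_synth_config")
}

#' Generate one chemical-like name
#'
#' Concatenates an optional numeric locant, two to five basic segments from
#' the shipped segment dictionary, and an optional suffix from the shipped
#' affix lists, occasionally decorated with a trailing hyphen-number. Every
#' generated name has a chemical segment composition ratio above 0.5 against
#' the shipped dictionary (redrawn otherwise). Draws from the current RNG
#' state; seed via `set.seed()` or [generate_corpus()].
#'
#' @param sd Segment dictionary (defaults to the shipped fixture).
#' @param affixes Affix lists (defaults to the shipped fixture).
#' @return List with elements `name` and `abbrev` (uppercase initials of the
#'   name's parts; always a subsequence of the name).
#' @export
generate_name <- function(sd = load_segment_dictionary(),
                          affixes = load_affixes()) {
  suffixes <- unlist(affixes$suffix, use.names = FALSE)
  for (attempt in 1:20) {
    parts <- character()
    if (runif(1) < 0.4) {
      loc <- as.character(sample(1:20, 1))
      if (runif(1) < 0.2) loc <- paste0(loc, ",", sample(1:20, 1))
      parts <- c(parts, loc, "-")
    }
    k <- sample(2:5, 1)
    segs <- sample(sd$set, k, replace = TRUE)
    parts <- c(parts, segs)
    if (runif(1) < 0.4) parts <- c(parts, sample(suffixes, 1))
    if (runif(1) < 0.15) parts <- c(parts, "-", as.character(sample(1:9, 1)))
    name <- paste(parts, collapse = "")
    if (composition_ratio(name, sd) > 0.5) {
      letters_only <- parts[grepl("^[a-z]", parts)]
      abbrev <- toupper(paste(substr(letters_only, 1, 1), collapse = ""))
      if (nchar(abbrev) >= 2 && verify_abbreviation(abbrev, name))
        return(list(name = name, abbrev = abbrev))
    }
  }
  list(name = "methyloxycalcium", abbrev = "MOC")  # unreachable fallback
}

# substitute placeholders and return text + mention rows (section offsets
# relative to the sentence start)
fill_template <- function(template, values, subtypes) {
  text <- template
  mentions <- list()
  for (key in names(values)) {
    tag <- paste0("{", key, "}")
    pos <- regexpr(tag, text, fixed = TRUE)
    if (pos < 0) next
    start <- pos - 1L  # 0-based
    text <- sub(tag, values[[key]], text, fixed = TRUE)
    mentions[[length(mentions) + 1L]] <- data.frame(
      start = start, end = start + nchar(values[[key]]),
      text = values[[key]], subtype = subtypes[[key]],
      stringsAsFactors = FALSE)
  }
  list(text = text, mentions = if (length(mentions))
    do.call(rbind, mentions) else NULL)
}

#' Generate a synthetic gold-annotated corpus
#'
#' @param cfg A [synth_config()].
#' @param sd,affixes Resources for [generate_name()].
#' @return List of [chem_document()] objects with gold mentions
#'   (`SYSTEMATIC` for generated names, `ABBREVIATION` for abbreviations).
#' @export
generate_corpus <- function(cfg = synth_config(),
                            sd = load_segment_dictionary(),
                            affixes = load_affixes()) {
  set.seed(cfg$seed)
  docs <- vector("list", cfg$n_documents)
  for (d in seq_len(cfg$n_documents)) {
    doc_id <- sprintf("SYN%05d", d)
    # title
    if (runif(1) < 0.7) {
      nm <- generate_name(sd, affixes)
      tf <- fill_template(sample(TITLE_TEMPLATES, 1),
                          list(N = nm$name), list(N = "SYSTEMATIC"))
      title <- tf$text
      tmen <- tf$mentions
    } else {
      title <- sample(TITLE_PLAIN, 1)
      tmen <- NULL
    }
    if (!is.null(tmen)) tmen$section <- "T"
    # abstract sentences
    sents <- character()
    amen <- list()
    add_sentence <- function(fill) {
      offset <- if (length(sents)) nchar(paste(sents, collapse = " ")) + 1L
                else 0L
      sents <<- c(sents, fill$text)
      if (!is.null(fill$mentions)) {
        m <- fill$mentions
        m$start <- m$start + offset
        m$end <- m$end + offset
        m$section <- "A"
        amen[[length(amen) + 1L]] <<- m
      }
    }
    n_names <- sample(cfg$names_per_doc[1]:cfg$names_per_doc[2], 1)
    with_abbrev <- runif(1) < cfg$abbreviation_rate
    for (s in seq_len(n_names)) {
      nm <- generate_name(sd, affixes)
      if (with_abbrev && s == 1L) {
        add_sentence(fill_template(
          ABBREV_TEMPLATE, list(N = nm$name, A = nm$abbrev),
          list(N = "SYSTEMATIC", A = "ABBREVIATION")))
        add_sentence(fill_template(
          ABBREV_USE_TEMPLATE, list(A = nm$abbrev),
          list(A = "ABBREVIATION")))
      } else {
        add_sentence(fill_template(
          sample(NAME_TEMPLATES, 1), list(N = nm$name),
          list(N = "SYSTEMATIC")))
      }
      if (runif(1) < cfg$distractor_rate)
        add_sentence(list(text = sample(DISTRACTOR_SENTENCES, 1),
                          mentions = NULL))
    }
    abstract <- paste(sents, collapse = " ")
    pieces <- lapply(c(list(tmen), amen), as_mentions)
    mentions <- do.call(rbind, pieces)
    docs[[d]] <- chem_document(doc_id, title, abstract, as_mentions(mentions))
  }
  docs
}
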