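---
title: "Chemical NER with chemner: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical NER with chemner: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chemner` recognises chemical entity mentions in scientific text. This
vignette explains the sequence-labelling model, the chemistry-aware
components around it, the parameters that matter, and the design decisions
taken where behaviour was genuinely open.

## The labelling model

Mentions are encoded per token with the BIO scheme: `B` begins a chemical
name, `I` continues it, `O` is outside. The labeller is a linear-chain
conditional random field (CRF): given token features and nine transition
weights, it models the conditional distribution of the whole label sequence
and is trained by maximum likelihood with an L2 penalty, optimised with
L-BFGS-B from a zero initialisation (so training is deterministic for fixed
data and ordering — no random restarts). Prediction uses Viterbi decoding;
per-token confidences are posterior marginals from forward–backward, so for
every token the marginals of `O`, `B` and `I` sum to one.

Two structural constraints are built into the model rather than enforced
afterwards: a sequence cannot start with `I`, and `O → I` transitions are
impossible. Every prediction is therefore a valid BIO sequence by
construction, under any regularisation strength.

The CRF engine is implemented in compiled code inside the package
(forward–backward, Viterbi and gradient computation in C++ via Rcpp; the
optimiser is `stats::optim`). Tunables:

* `lambda` (default 1.0) — L2 strength. The default mirrors common CRF
  toolkit practice; heavier values shrink towards uniform marginals but can
  never produce invalid BIO output.
* `maxit` (default 200) — L-BFGS-B iteration cap.

Gold mentions whose boundaries fall inside a token are expanded to the whole
token with a warning. The alternative — splitting the token — was rejected
because it would change the feature space between training and prediction.

## Pre-processing

**Sentence splitting.** The *scientific* mode places boundaries after
`.`/`!`/`?` followed by whitespace, with a fixed exception list (`e.g.`,
`i.e.`, `et al.`, ...), and does **not** require the next sentence to start
with an uppercase character — scientific text legitimately begins sentences
with entities like *p53*. The *general* mode adds the uppercase-or-digit
requirement. These are rule-based approximations keyed to the two published
behavioural contrasts; no statistical splitter is embedded.

**Tokenisation.** The *chemistry* mode works on whitespace-delimited chunks
and keeps them intact — including digits, commas, hyphens and balanced
internal brackets, so `4,9-Diazadodecane-1,12-diamine` and
`bis-(4-nitrophenyl)` each stay one token — with two exceptions: sentence
punctuation and unbalanced brackets at chunk edges detach (so `(STMP)`
yields `(`, `STMP`, `)`, which the abbreviation heuristic relies on), and a
hyphen joining a chemical fragment to a plain English word from a closed
suffix list (`induced`, `treated`, `mediated`, ...) splits *before* the
hyphen, keeping the hyphen attached to the word: `GSK214a-induced` →
`GSK214a`, `-induced`. The *general* mode splits at every punctuation
character. Token offsets are 0-based half-open code-point offsets in the
section's coordinate space (title and abstract are separate spaces), and
re-assembling surfaces with the original gaps reproduces the text exactly.

**Tagging.** Lemmas, POS and chunk tags come from a pluggable tagger
interface (surfaces in, three parallel annotation vectors out), so a
statistical biomedical tagger can be dropped in. The built-in fallback is
deterministic: closed-class lookup plus suffix rules for POS, inflection
stripping for lemmas, and a regular NP/VP/PP grammar over the POS sequence
for chunks.

## The feature set

The default tier is weakly chemical-indicative: character 2/3/4-grams of the
token; surface, shape-normalised, lemma, POS and lemma:POS unigrams and
bigrams within a distance of two of the active token; the active token's
chunk tag and the surface of the final token of its enclosing chunk; and 21
orthographic flags (capitalisation, digit content, bracket and punctuation
occurrence, Greek letter names as substrings).

The knowledge-rich tier adds:

* **Dictionary features.** Lexicons are compiled with a normalisation that
  lower-cases letters, maps digits to `0` and everything else to `_`
  (`HES-HEMA` → `hes_hema`). Matching is greedy leftmost-longest over the
  normalised *lemma* sequence — the lemma reading (rather than raw surface)
  is what reproduces the documented tagging of plural contexts such as
  *microspheres* → *microsphere*, and is recorded here as an assumption.
  The resulting BIO labels contribute unigrams/bigrams and surface:label
  combinations within the ±2 window.
* **Affix matches.** Boundary substrings of sizes 2–4 looked up
  case-insensitively in prefix and suffix lists (`diisopropyl` → prefix
  `di`, suffix `yl`).
* **Element symbols.** Exact case-sensitive membership in the 118-symbol
  periodic table (`Fe` yes, `fe`/`NO` no).
* **Word shapes.** Full and brief variants (`0_a_0_A_a`). One documented
  shape example in the source material contains an internal space that
  cannot arise from the stated per-character mapping; it is treated as a
  typesetting artifact, and the mapping is applied per code point. A related
  description suggests compressing runs of digits in normalised context
  tokens, but its own printed example (`AAA000a`) is uncompressed; the
  example is followed.
* **Basic-segment counts**, bucketed at `0,1,2,3,4,5+` to keep the
  categorical feature space bounded.

Feature extraction is a pure function of (sentence, index, resources,
configuration); the enriched vector is a superset of the default vector by
construction.

## Segment decomposition and the composition ratio

A token is first split at letter/digit/punctuation boundaries. Each maximal
letter run is covered left-to-right by greedy longest matches against the
segment dictionary; residues become unmatched fragments. Digit runs are
numeric fragments, punctuation runs are delimiters. The exact backtracking
behaviour of the original registry procedure on failed matches is not
published; leftmost-longest with residue fragments is adopted and checked
against a brute-force cover oracle in the tests.

Two quantities are derived, and they deliberately treat digits differently:

* `count_segments` counts matched, unmatched **and numeric** fragments
  (`10-acetoxyactinidine` → `10, acet, oxy, actin, idine` = 5), excluding
  delimiters;
* `composition_ratio` counts only **matched characters** in the numerator
  over all characters (`2-methoxyestradiol` → 16/18 ≈ 0.89).

This split reading is the only one consistent with both documented example
tables. Ratios are compared at two decimal places, rounded half-up.
Matching is case-insensitive.

## Post-processing heuristics

Both heuristics only ever add chemical labels — the chemical token set after
post-processing is a superset of the set before (verified as a property
test).

**Abbreviation recognition.** For a recognised mention ending at token
`t_i`: if `t_(i+1)` is `(`, `t_(i+3)` is `)` and `t_(i+2)` is labelled `O`,
then `t_(i+2)` is a candidate abbreviation; if its characters occur
sequentially (case-insensitively) within the mention text, every occurrence
of that surface in the document is relabelled `B`. Multi-token abbreviations
are structurally unsupported (the rule fixes `t_(i+3)` to `)`).

**Composition-based relabelling.** An `O` token with confidence strictly
below `t1` and composition ratio strictly above `t2` becomes a single-token
`B` mention. The strict inequalities follow the rule's published wording;
adjacent relabelled tokens are *not* merged, which is the minimal
interpretation of a token-level rule. Defaults `t1 = 0.93`, `t2 = 0.9` are
the settings reported to optimise precision and F1; they are configuration,
not re-derived here.

## Evaluation

CEM scoring is exact-span and type-agnostic: a predicted `(section, start,
end)` must match a gold mention exactly. CDI scoring deduplicates mention
strings per document (case-sensitive, keeping the maximum confidence) and
compares string sets. Precision, recall and F1 use the 0/0 → 0 convention.
Micro averaging pools counts over documents (and is therefore invariant to
how documents are partitioned); macro averaging takes the mean of
per-document metrics, excluding documents with empty gold *and* empty
predictions — the reference evaluation tool's exact edge-case convention is
unpublished, so this choice is recorded in the report metadata. CDI ranking
by maximum confidence with ties broken by string is likewise an
implementation convention, not an external fact.

## The synthetic corpus, and what passing tests mean

`generate_corpus()` emulates abstracts with sectioned text and exact gold
offsets: template sentences embed generated names; names concatenate an
optional numeric locant, 2–5 basic segments from the shipped dictionary and
an optional chemical suffix, guaranteeing a composition ratio above 0.5;
abbreviation documents introduce `long name (ABBR)` patterns whose
abbreviation passes the subsequence check and recurs later; distractor
sentences contain no chemicals. Default rates (30% abbreviation documents,
50% distractor insertion, 2–4 names per document) were chosen once as
plausible for abstract-like text.

Because the name grammar draws only from the shipped segment dictionary and
affix lists, the knowledge-rich features are informative *by construction*.
That makes the feature→performance link testable — and it is why end-to-end
results on this corpus (the test suite trains on 400 documents and evaluates
on 100, reaching mention-level micro-F1 ≥ 0.80, in fact 1.0 at the tested
seed) must not be read as corpus benchmarks. Real chemical text has
out-of-dictionary morphology, ambiguous umbrella terms, formula and
identifier subtypes and annotation-guideline quirks that the generator does
not model. What the synthetic experiments do establish: offsets survive the
whole pipeline, training is deterministic, separable signal is learned, and
each post-processing heuristic has its intended directional effect (the
abbreviation pass strictly raises token-level recall on abbreviation-heavy
documents whose abbreviations never occur in training).

## Numerical and degenerate-input choices

* Forward–backward and Viterbi run in log space; disallowed transitions are
  hard `-Inf` masks, not large negative constants.
* Mention confidence is the minimum of member-token confidences — a
  conservative score for CDI ranking.
* Prediction-file ranks order by descending confidence with `(section,
  start, end)` tie-breaks; confidences serialise with six decimals so output
  files are byte-stable.
* Empty text yields empty sentence lists; empty lexicons tag all-`O`;
  delimiter-only tokens have zero segments; the composition ratio of an
  empty token is an error rather than a convention.
* Features unseen at training time are silently dropped at prediction; a
  differing feature *configuration* (as opposed to vocabulary) is an error,
  detected via the fingerprint stored with the model.

## Known limitations

* The splitter/tokeniser are rule approximations; they reproduce the
  documented behavioural contrasts but not the full behaviour of any
  specific external tool.
* The fallback tagger is intentionally simple; serious use should plug in a
  trained biomedical tagger through the tagger interface.
* The shipped segment dictionary is a 15-entry demonstration fixture; the
  full ~3,300-entry registry dictionary must be supplied by the user, as
  must real lexicons (ChEBI, DrugBank, CTD, PubChem, Jochem — their contents
  are not redistributed here).
* Mention subtypes are carried on gold annotations for error breakdowns but
  are not predicted; the recogniser is single-class.
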