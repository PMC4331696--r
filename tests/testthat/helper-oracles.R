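# Independent brute-force oracles used to cross-check the greedy matchers.

# enumerate all matching token spans, then repeatedly take the span that
# starts earliest (ties: longest) at/after the current position
oracle_tag <- function(tokens, keys) {
  n <- length(tokens)
  spans <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (paste(tokens[i:j], collapse = " ") %in% keys)
      spans[[length(spans) + 1L]] <- c(i, j)
  }
  labels <- rep("O", n)
  pos <- 1L
  while (pos <= n) {
    cand <- Filter(function(s) s[1] >= pos, spans)
    if (!length(cand)) break
    starts <- vapply(cand, `[`, integer(1), 1)
    lens <- vapply(cand, function(s) s[2] - s[1], integer(1))
    pick <- cand[[order(starts, -lens)[1]]]
    labels[pick[1]] <- "B"
    if (pick[2] > pick[1]) labels[(pick[1] + 1):pick[2]] <- "I"
    pos <- pick[2] + 1L
  }
  labels
}

# brute-force leftmost-longest cover of a letter run by dictionary spans
oracle_cover <- function(run, set) {
  n <- nchar(run)
  spans <- list()
  for (i in seq_len(n)) for (j in i:n)
    if (substr(run, i, j) %in% set) spans[[length(spans) + 1L]] <- c(i, j)
  chosen <- list()
  pos <- 1L
  repeat {
    cand <- Filter(function(s) s[1] >= pos, spans)
    if (!length(cand)) break
    starts <- vapply(cand, `[`, integer(1), 1)
    lens <- vapply(cand, function(s) s[2] - s[1], integer(1))
    pick <- cand[[order(starts, -lens)[1]]]
    chosen[[length(chosen) + 1L]] <- pick
    pos <- pick[2] + 1L
  }
  chosen
}
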