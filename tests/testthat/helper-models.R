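# Shared fixtures built in code.

# count_tables with hand-set bigram counts (keys "prev nxt"; null_token() for
# a terminus), bypassing corpus counting -- used to pin down the smoothing
# arithmetic on exact numbers.
manual_counts <- function(alphabet, bigrams = list(), monogram = NULL,
                          n_unique = 1L) {
  ctx <- c(alphabet, null_token())
  big <- matrix(0L, length(ctx), length(ctx),
                dimnames = list(prev = ctx, nxt = ctx))
  for (key in names(bigrams)) {
    pn <- strsplit(key, " ", fixed = TRUE)[[1]]
    big[pn[1], pn[2]] <- as.integer(bigrams[[key]])
  }
  mono <- stats::setNames(integer(length(alphabet)), alphabet)
  if (!is.null(monogram)) mono[names(monogram)] <- as.integer(monogram)
  structure(list(monogram = mono, bigram = big,
                 trigram = stats::setNames(integer(0), character(0)),
                 n_unique_das = n_unique, alphabet = alphabet),
            class = "count_tables")
}

# A small trained model with irregular counts, for ratio/probability tests.
toy_trained_model <- function(k = 0.1) {
  corpus <- list(c("A", "B"), c("A", "B", "A"), c("C", "A"), "B",
                 c("B", "B", "C"), c("A", "C", "C", "B"))
  build_model(count_ngrams(corpus), k = k)
}

# Random corpus of architectures over a given alphabet (not necessarily
# unique), for property-style tests.
random_corpus <- function(n, alphabet, max_len = 6) {
  lapply(seq_len(n), function(i) {
    len <- sample.int(max_len, 1L)
    alphabet[sample.int(length(alphabet), len, replace = TRUE)]
  })
}

# Brute-force acceptance-ratio oracle: full architecture probabilities
# before and after the move, no cancellation.
brute_force_ratio <- function(model, da_from, da_to) {
  exp(architecture_log_probability(model, da_to) -
        architecture_log_probability(model, da_from))
}

write_temp_annotations <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
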