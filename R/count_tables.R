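# n-gram count tables over a set of unique architectures.
#
# Monograms are counted with multiplicity within each unique DA (a DA
# [A, B, A] contributes 2 to A). Bigrams include the NULL-boundary pairs
# (NULL, d1) and (dn, NULL), so a length-n DA contributes n + 1 bigrams.
# Trigrams are taken from the NULL-padded sequence (NULL, d1, ..., dn, NULL),
# so a length-n DA contributes n trigrams; a single-domain DA contributes
# (NULL, d1, NULL).

#' Count n-grams over a set of domain architectures
#'
#' Computes monogram, bigram and trigram counts over a corpus of (typically
#' unique) domain architectures. Bigram and trigram counts include pairs and
#' triples with the NULL terminus sentinel, which is how the first-order
#' model sees architecture boundaries.
#'
#' @param corpus A list of character vectors, each an architecture in N- to
#'   C-terminal order. Usually the output of [unique_architectures()].
#' @param alphabet Optional character vector fixing the alphabet (and hence
#'   the bigram matrix dimensions). Defaults to the sorted set of tokens
#'   observed in `corpus`.
#' @param monogram_mode `"multiplicity"` (default) counts every occurrence of
#'   a token across unique DAs; `"presence"` counts each DA containing the
#'   token once.
#' @return An object of class `count_tables` with elements `monogram` (named
#'   integer vector over the alphabet), `bigram` (integer matrix over
#'   alphabet + NULL, rows = preceding token), `trigram` (named integer
#'   vector, keys `"a b c"`), `n_unique_das` and `alphabet`.
#' @examples
#' ct <- count_ngrams(list(c("A", "B"), c("A", "B", "A")))
#' ct$bigram["A", "B"]
#' @export
count_ngrams <- function(corpus, alphabet = NULL,
                         monogram_mode = c("multiplicity", "presence")) {
  monogram_mode <- match.arg(monogram_mode)
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of architectures")
  lapply(corpus, assert_architecture)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(corpus, use.names = FALSE)))
  } else {
    assert_alphabet(alphabet)
    lapply(corpus, assert_architecture, alphabet = alphabet)
  }
  ctx <- c(alphabet, .NULL_TOKEN)
  nd <- length(alphabet)

  bigram <- matrix(0L, nrow = nd + 1L, ncol = nd + 1L,
                   dimnames = list(prev = ctx, nxt = ctx))
  mono <- setNames(integer(nd), alphabet)
  tri <- new.env(parent = emptyenv())

  for (da in corpus) {
    n <- length(da)
    padded <- c(.NULL_TOKEN, da, .NULL_TOKEN)
    # bigrams over the padded sequence: n + 1 pairs
    pi_ <- match(padded[seq_len(n + 1L)], ctx)
    ni_ <- match(padded[1L + seq_len(n + 1L)], ctx)
    for (j in seq_len(n + 1L))
      bigram[pi_[j], ni_[j]] <- bigram[pi_[j], ni_[j]] + 1L
    if (monogram_mode == "multiplicity") {
      tt <- table(da)
      mono[names(tt)] <- mono[names(tt)] + as.integer(tt)
    } else {
      u <- unique(da)
      mono[u] <- mono[u] + 1L
    }
    # trigrams over the padded sequence: n triples
    for (j in seq_len(n)) {
      key <- paste(padded[j], padded[j + 1L], padded[j + 2L])
      tri[[key]] <- (if (is.null(tri[[key]])) 0L else tri[[key]]) + 1L
    }
  }

  keys <- sort(ls(tri))
  trigram <- setNames(vapply(keys, function(k) tri[[k]], integer(1)), keys)
  structure(
    list(monogram = mono, bigram = bigram, trigram = trigram,
         n_unique_das = length(corpus), alphabet = alphabet),
    class = "count_tables"
  )
}

#' @export
print.count_tables <- function(x, ...) {
  cat("Count tables:", length(x$alphabet), "domain superfamilies,",
      x$n_unique_das, "unique DAs\n")
  cat("  bigram total:", sum(x$bigram),
      "| distinct observed bigrams:", sum(x$bigram > 0L), "\n")
  cat("  trigram total:", sum(x$trigram), "\n")
  invisible(x)
}
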