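# First-order (bigram) model of domain architectures.
#
# The probability of a DA d1..dn is approximated as
#   p(d1 | NULL) p(d2 | d1) ... p(NULL | dn),
# with the NULL sentinel marking the termini. Conditionals are estimated
# from bigram counts over unique architectures with add-k smoothing:
#   p(y | x) = (C(x, y) + k) / (sum_y' C(x, y') + k * |continuations(x)|).
# The continuation set of every context is alphabet + NULL, except that the
# (NULL, NULL) continuation is excluded so the empty architecture has
# probability zero and the model is a proper distribution over non-empty
# sequences. With k = 0 the unsmoothed maximum-likelihood estimate is
# recovered.

#' Build a smoothed first-order model from n-gram counts
#'
#' @param counts A [count_ngrams()] result.
#' @param alphabet Optional alphabet override; defaults to `counts$alphabet`.
#' @param k Add-k pseudocount, a nonnegative number, or `"default"` for
#'   `1 / N_D` where `N_D` is the alphabet size. The default offsets the
#'   `O(N_D)` pseudocounts added per context while keeping all transitions
#'   possible, so the chain remains irreducible.
#' @return An object of class `first_order_model` with elements `alphabet`,
#'   `k`, `counts`, `prob` and `logp` (matrices over alphabet + NULL, rows =
#'   conditioning context), and `n_unique_das`.
#' @examples
#' ct <- count_ngrams(list(c("A", "B"), "A"))
#' m <- build_model(ct, k = "default")
#' conditional_probability(m, "A", "B")
#' @export
build_model <- function(counts, alphabet = NULL, k = "default") {
  if (!inherits(counts, "count_tables"))
    stop("counts must be a count_tables object")
  if (is.null(alphabet)) alphabet <- counts$alphabet
  assert_alphabet(alphabet)
  nd <- length(alphabet)
  k <- resolve_pseudocount(k, nd)

  ctx <- c(alphabet, .NULL_TOKEN)
  big <- counts$bigram
  if (!identical(rownames(big), ctx))
    stop("count table alphabet does not match the requested alphabet")

  ncont <- rep(nd + 1L, nd + 1L)
  ncont[nd + 1L] <- nd          # NULL context: (NULL, NULL) excluded
  smoothed <- big + k
  smoothed[nd + 1L, nd + 1L] <- 0
  denom <- rowSums(big) + k * ncont
  prob <- smoothed / denom
  dimnames(prob) <- list(prev = ctx, nxt = ctx)

  new_first_order_model(alphabet, k, prob, counts = counts,
                        n_unique_das = counts$n_unique_das)
}

#' Build a first-order model directly from a conditional probability table
#'
#' Used mainly by the synthetic-corpus generator, where the ground truth is
#' a probability table rather than counts. Rows must sum to one over the
#' continuation set and the (NULL, NULL) cell must be zero.
#'
#' @param prob Square matrix over alphabet + NULL (rows = context), row
#'   names and column names set to `c(alphabet, null_token())`.
#' @param alphabet Character vector of domain tokens.
#' @param k Pseudocount recorded on the model (informational; the table is
#'   used as given).
#' @return A `first_order_model`.
#' @export
model_from_probabilities <- function(prob, alphabet, k = 0) {
  assert_alphabet(alphabet)
  ctx <- c(alphabet, .NULL_TOKEN)
  if (!is.matrix(prob) || !identical(rownames(prob), ctx) ||
      !identical(colnames(prob), ctx))
    stop("prob must be a matrix with dimnames c(alphabet, null_token())")
  if (prob[.NULL_TOKEN, .NULL_TOKEN] != 0)
    stop("p(NULL | NULL) must be zero (empty architectures are impossible)")
  if (any(prob < 0))
    stop("negative probabilities")
  if (max(abs(rowSums(prob) - 1)) > 1e-8)
    stop("rows of prob must sum to 1")
  new_first_order_model(alphabet, k, prob, counts = NULL, n_unique_das = NA_integer_)
}

new_first_order_model <- function(alphabet, k, prob, counts, n_unique_das) {
  structure(
    list(alphabet = alphabet, k = k, prob = prob, logp = log(prob),
         counts = counts, n_unique_das = n_unique_das),
    class = "first_order_model"
  )
}

resolve_pseudocount <- function(k, nd) {
  if (identical(k, "default")) return(1 / nd)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("k must be a single nonnegative number or \"default\"")
  as.numeric(k)
}

#' @export
print.first_order_model <- function(x, ...) {
  nd <- length(x$alphabet)
  cat("First-order domain architecture model\n")
  cat("  alphabet size N_D =", nd, " pseudocount k =", format(x$k), "\n")
  if (!is.null(x$counts))
    cat("  trained on", x$n_unique_das, "unique DAs;",
        sum(x$counts$bigram > 0L), "observed bigrams\n")
  if (x$k == 0 && any(x$prob[seq_len(nd), ] == 0))
    cat("  note: k = 0 and some conditionals are exactly 0;",
        "the chain is not irreducible\n")
  invisible(x)
}

# Index of a token (or the NULL sentinel) in the context set; errors on
# unknown tokens.
token_index <- function(model, token, what = "token") {
  i <- match(token, c(model$alphabet, .NULL_TOKEN))
  if (anyNA(i))
    stop(what, " not in alphabet: ",
         paste(token[is.na(i)], collapse = ", "))
  i
}

#' Smoothed conditional probability p(next | prev)
#'
#' @param model A `first_order_model`.
#' @param prev,nxt Domain tokens, or [null_token()] for a terminus. The pair
#'   (NULL, NULL) is invalid: an architecture has at least one domain.
#' @return The smoothed conditional probability, in `[0, 1]`.
#' @export
conditional_probability <- function(model, prev, nxt) {
  i <- token_index(model, prev, "prev token")
  j <- token_index(model, nxt, "next token")
  nd <- length(model$alphabet)
  if (i == nd + 1L && j == nd + 1L)
    stop("invalid bigram: (NULL, NULL) has no probability")
  model$prob[i, j]
}

#' First-order log-probability of a domain architecture
#'
#' Computes `log p(d1 | NULL) + log p(d2 | d1) + ... + log p(NULL | dn)`:
#' exactly `n + 1` conditional factors for a length-`n` architecture.
#'
#' @param model A `first_order_model`.
#' @param da Character vector of domain tokens (N- to C-terminal).
#' @return The log-probability (<= 0; `-Inf` possible when `k = 0`).
#' @export
architecture_log_probability <- function(model, da) {
  assert_architecture(da)
  idx <- token_index(model, da)
  nd1 <- length(model$alphabet) + 1L
  path <- c(nd1, idx, nd1)
  n1 <- length(da) + 1L
  sum(model$logp[cbind(path[seq_len(n1)], path[1L + seq_len(n1)])])
}

#' Acceptance ratio for inserting a domain
#'
#' Ratio `p(t) / p(s)` where `t` is the architecture obtained from `s` by
#' inserting `token` at insertion site `site` (0 = before the first domain,
#' `n` = after the last). Under the first-order factorisation all but three
#' factors cancel, leaving
#' `p(x | left) p(right | x) / p(right | left)`
#' with `left`/`right` the flanking tokens (NULL at a terminus).
#'
#' @param model A `first_order_model`.
#' @param da The current architecture (character vector).
#' @param site Insertion site, integer in `0..length(da)`.
#' @param token The gained domain token.
#' @return Nonnegative ratio; equals `exp(logP(t) - logP(s))` exactly.
#' @export
insertion_ratio <- function(model, da, site, token) {
  assert_architecture(da)
  n <- length(da)
  if (!is.numeric(site) || length(site) != 1L || site < 0 || site > n)
    stop("site must be in 0..n")
  site <- as.integer(site)
  nd1 <- length(model$alphabet) + 1L
  x <- token_index(model, token)
  if (x == nd1) stop("cannot insert the NULL sentinel")
  left <- if (site == 0L) nd1 else token_index(model, da[site])
  right <- if (site == n) nd1 else token_index(model, da[site + 1L])
  num <- model$logp[left, x] + model$logp[x, right]
  den <- model$logp[left, right]
  if (is.infinite(num) && num < 0) return(0)
  if (is.infinite(den) && den < 0) return(Inf)
  exp(num - den)
}

#' Acceptance ratio for deleting a domain
#'
#' Ratio `p(t) / p(s)` where `t` is obtained from `s` by deleting the domain
#' at position `pos` (1-based). The cancelled form is
#' `p(right | left) / (p(deleted | left) p(right | deleted))`.
#' Deletion from a single-domain architecture is vetoed by the simulator, not
#' here; `pos` must satisfy `length(da) >= 2`.
#'
#' @param model A `first_order_model`.
#' @param da The current architecture, length >= 2.
#' @param pos Position of the deleted domain, in `1..length(da)`.
#' @return Nonnegative ratio; equals `exp(logP(t) - logP(s))` exactly.
#' @export
deletion_ratio <- function(model, da, pos) {
  assert_architecture(da)
  n <- length(da)
  if (n < 2L) stop("deletion requires an architecture of length >= 2")
  if (!is.numeric(pos) || length(pos) != 1L || pos < 1 || pos > n)
    stop("pos must be in 1..n")
  pos <- as.integer(pos)
  nd1 <- length(model$alphabet) + 1L
  d <- token_index(model, da[pos])
  left <- if (pos == 1L) nd1 else token_index(model, da[pos - 1L])
  right <- if (pos == n) nd1 else token_index(model, da[pos + 1L])
  num <- model$logp[left, right]
  den <- model$logp[left, d] + model$logp[d, right]
  if (is.infinite(num) && num < 0) return(0)
  if (is.infinite(den) && den < 0) return(Inf)
  exp(num - den)
}

#' Number of states adjacent to an architecture of length n
#'
#' A length-`n` architecture (`n >= 2`) has `n` deletion neighbours and
#' `(n + 1) * N_D` insertion neighbours, i.e. `n + (n + 1) * N_D` adjacent
#' states. Deletions from a single-domain architecture are forbidden (the
#' architecture may not go extinct), so for `n = 1` there are `2 * N_D`
#' adjacent states.
#'
#' @param n Architecture length, >= 1.
#' @param n_d Alphabet size, >= 1.
#' @return Integer count of adjacent states.
#' @export
adjacent_state_count <- function(n, n_d) {
  if (!is.numeric(n) || any(n < 1)) stop("n must be >= 1")
  if (!is.numeric(n_d) || any(n_d < 1)) stop("n_d must be >= 1")
  ifelse(n == 1, 2 * n_d, n + (n + 1) * n_d)
}
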