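# Synthetic ground-truth corpora. A known first-order model is sampled, a
# corpus of unique architectures is drawn from it by ancestral sampling, and
# the whole pipeline (training, simulation, evaluation) can then be tested
# offline against the known truth.

#' Specification for a synthetic ground-truth generator
#'
#' @param alphabet_size Number of domain superfamily tokens.
#' @param transition_sparsity Fraction of token-to-token transitions forced
#'   to zero, in `[0, 1)`. Termination (`p(NULL | x)`) and start
#'   (`p(x | NULL)`) probabilities are never zeroed, so every token remains
#'   reachable and every architecture can terminate: the model stays
#'   irreducible on its support.
#' @param termination_strength Mean termination probability per context;
#'   the expected architecture length is approximately its reciprocal.
#'   Per-context termination probabilities are drawn around this mean and
#'   bounded away from zero, so the expected length is finite.
#' @param corpus_size Number of unique architectures to draw.
#' @param weight_concentration Gamma shape for the random transition weights.
#'   Values below 1 give right-skewed, Zipf-like conditional distributions,
#'   as observed for genuine domain combinations; 1 gives flat Dirichlet
#'   rows.
#' @param tandem_propensity Fraction of tokens that are tandem-prone: their
#'   self-transition gets a boosted weight, emulating repeat-forming
#'   superfamilies (immunoglobulins, ARM repeats, zinc fingers, ...), which
#'   dominate tandem-array statistics in genuine data.
#' @param seed Integer seed.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(alphabet_size, transition_sparsity = 0.9,
                           termination_strength = 0.25, corpus_size = 200L,
                           weight_concentration = 0.5,
                           tandem_propensity = 0.2, seed = 1L) {
  if (alphabet_size < 1) stop("alphabet_size must be >= 1")
  if (transition_sparsity < 0 || transition_sparsity >= 1)
    stop("transition_sparsity must be in [0, 1)")
  if (termination_strength <= 0.01 || termination_strength >= 1)
    stop("termination_strength must be in (0.01, 1) so expected length is finite")
  if (corpus_size < 1) stop("corpus_size must be >= 1")
  if (weight_concentration <= 0) stop("weight_concentration must be positive")
  if (tandem_propensity < 0 || tandem_propensity > 1)
    stop("tandem_propensity must be in [0, 1]")
  structure(list(alphabet_size = as.integer(alphabet_size),
                 transition_sparsity = transition_sparsity,
                 termination_strength = termination_strength,
                 corpus_size = as.integer(corpus_size),
                 weight_concentration = weight_concentration,
                 tandem_propensity = tandem_propensity,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Sample a ground-truth first-order model
#'
#' Draws a random conditional probability table over alphabet + NULL: token
#' weights per context are independent Gamma draws (a Dirichlet row), the
#' requested fraction of token-to-token cells is zeroed, and each context's
#' termination probability is drawn around `termination_strength` (Beta,
#' clamped to at least a quarter of the mean) before the token weights are
#' renormalised into the remaining mass.
#'
#' @param spec A [generator_spec()].
#' @return A `first_order_model` whose `prob` table is the exact ground
#'   truth (no counts attached, `k = 0`).
#' @export
sample_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  nd <- spec$alphabet_size
  alphabet <- sprintf("SF%04d", seq_len(nd))
  ctx <- c(alphabet, .NULL_TOKEN)
  prob <- matrix(0, nd + 1L, nd + 1L, dimnames = list(prev = ctx, nxt = ctx))

  theta <- spec$termination_strength
  # per-context termination probabilities, bounded away from 0 and 1
  conc <- 50
  term <- rbeta(nd, theta * conc, (1 - theta) * conc)
  term <- pmin(pmax(term, theta / 4), 0.9)

  shp <- spec$weight_concentration
  # heavy-tailed per-token promiscuity: a transition (i, j) is allowed with
  # probability proportional to s_i * s_j, so a few hub tokens combine with
  # many partners while most tokens have only a handful -- the degree
  # structure of genuine domain co-occurrence networks
  s <- stats::rlnorm(nd, meanlog = 0, sdlog = 1)
  s <- s / mean(s)
  if (spec$transition_sparsity > 0) {
    keep_p <- pmin(1, (1 - spec$transition_sparsity) * outer(s, s))
    zero_mask <- matrix(runif(nd * nd), nd, nd) >= keep_p
  } else {
    zero_mask <- matrix(FALSE, nd, nd)
  }
  # repeat-forming tokens are drawn from the most promiscuous (and hence most
  # frequent) tokens, as for genuine repeat superfamilies (immunoglobulins,
  # zinc fingers, ...), and terminate less readily so arrays can run long
  n_prone <- round(spec$tandem_propensity * nd)
  tandem_prone <- rep(FALSE, nd)
  if (n_prone > 0)
    tandem_prone[order(-s)[seq_len(n_prone)]] <- TRUE
  # repeat regions terminate less readily, some much less: the spread gives
  # superfamilies their characteristic array lengths
  term[tandem_prone] <- term[tandem_prone] * (0.15 + 0.6 * runif(n_prone))
  for (i in seq_len(nd)) {
    w <- rgamma(nd, shape = shp)
    w[zero_mask[i, ]] <- 0
    if (!tandem_prone[i] && spec$transition_sparsity > 0 && nd > 1L)
      w[i] <- 0        # most superfamilies do not form tandem arrays
    if (sum(w) == 0) {                              # keep the row usable
      ok <- if (!tandem_prone[i] && spec$transition_sparsity > 0 && nd > 1L)
        setdiff(seq_len(nd), i) else seq_len(nd)
      w[ok[sample.int(length(ok), 1L)]] <- 1
    }
    if (tandem_prone[i] && sum(w[-i]) > 0) {
      # repeat-forming token: strong self-transition, wide spread of
      # characteristic array sizes across superfamilies
      w[i] <- (0.4 + 8.6 * runif(1)) * sum(w[-i])
    }
    prob[i, seq_len(nd)] <- (1 - term[i]) * w / sum(w)
    prob[i, nd + 1L] <- term[i]
  }
  w0 <- rgamma(nd, shape = shp)
  w0 <- w0 + 1e-6 * max(w0)        # every token can start an architecture
  prob[nd + 1L, seq_len(nd)] <- w0 / sum(w0)      # p(NULL | NULL) = 0

  model_from_probabilities(prob, alphabet, k = 0)
}

#' Closed-form expected architecture length under a first-order model
#'
#' Treats generation as an absorbing Markov chain (tokens transient, NULL
#' absorbing): with `Q` the token-to-token block and `r0` the start
#' distribution, the expected length is `r0' (I - Q)^{-1} 1`.
#'
#' @param model A `first_order_model`.
#' @return Expected length of an ancestral-sampled architecture.
#' @export
expected_architecture_length <- function(model) {
  nd <- length(model$alphabet)
  Q <- model$prob[seq_len(nd), seq_len(nd), drop = FALSE]
  r0 <- model$prob[nd + 1L, seq_len(nd)]
  as.numeric(r0 %*% solve(diag(nd) - Q, rep(1, nd)))
}

#' Draw a corpus of unique architectures from a model
#'
#' Ancestral sampling: the first token is drawn from `p(. | NULL)`, then
#' successive tokens from `p(. | previous)` until NULL is drawn. Duplicates
#' are re-drawn until `corpus_size` distinct architectures have been
#' produced or a retry cap is hit (the model's support is then too small or
#' too concentrated for the requested corpus).
#'
#' @param model A `first_order_model`.
#' @param corpus_size Number of unique architectures.
#' @param unique Deduplicate (default). With `FALSE`, returns `corpus_size`
#'   independent draws with duplicates retained.
#' @param max_tries Retry cap (total draws), default `100 * corpus_size`.
#' @return List of architectures; when `unique`, sorted lexicographically.
#' @export
sample_corpus <- function(model, corpus_size, unique = TRUE,
                          max_tries = 100L * corpus_size) {
  nd <- length(model$alphabet)
  cum <- t(apply(model$prob, 1L, cumsum))
  draw_one <- function() {
    out <- character(0)
    i <- nd + 1L
    repeat {
      j <- which(runif(1) <= cum[i, ])[1]
      if (j == nd + 1L) {
        if (length(out) == 0L) next      # cannot happen: p(NULL|NULL) = 0
        return(out)
      }
      out <- c(out, model$alphabet[j])
      i <- j
      if (length(out) > 10000L) stop("runaway architecture; check the model")
    }
  }
  if (!unique) return(lapply(seq_len(corpus_size), function(r) draw_one()))
  seen <- new.env(parent = emptyenv())
  out <- vector("list", corpus_size)
  got <- 0L; tries <- 0L
  while (got < corpus_size) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("retry cap exceeded after ", got, " unique architectures; ",
           "the model cannot support a corpus of size ", corpus_size)
    da <- draw_one()
    key <- paste(da, collapse = " ")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- da
    }
  }
  unique_architectures(out)
}

#' Ready-made synthetic fixtures
#'
#' Fixed-seed ground-truth model + corpus pairs emulating the qualitative
#' shape of genuine metazoan training sets (right-skewed lengths, median
#' around 3, mean between 3 and 6) at sizes small enough for routine
#' testing: `"small"` has 20 tokens and 200 unique architectures, `"medium"`
#' 150 tokens and 3000. Both are byte-identical across runs.
#'
#' @param preset `"small"` or `"medium"`.
#' @return List with `model` (ground truth), `corpus` (list of unique
#'   architectures) and `spec`.
#' @export
make_paperlike_fixture <- function(preset = c("small", "medium")) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    small = generator_spec(alphabet_size = 20, transition_sparsity = 0.8,
                           termination_strength = 0.35, corpus_size = 200L,
                           weight_concentration = 0.45, seed = 101L),
    medium = generator_spec(alphabet_size = 150, transition_sparsity = 0.985,
                            termination_strength = 0.66, corpus_size = 3000L,
                            weight_concentration = 0.45, seed = 202L))
  model <- sample_ground_truth(spec)
  corpus <- sample_corpus(model, spec$corpus_size)
  list(model = model, corpus = corpus, spec = spec)
}
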