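# Evaluation statistics comparing two sets of domain architectures
# (typically genuine vs simulated), computed identically on both sets.
# Correlations pair the two sets over the union of observed keys, with
# zeros filled in for keys absent from one set (an intersection-only mode is
# available where noted).

set_as_list <- function(x) {
  if (inherits(x, "training_corpus")) return(x$unique_architectures)
  if (inherits(x, "replicate_set")) return(x$finals)
  if (is.character(x)) return(list(x))
  x
}

paired_counts <- function(a, b, intersect_only = FALSE) {
  keys <- if (intersect_only) intersect(names(a), names(b))
          else sort(union(names(a), names(b)))
  va <- setNames(numeric(length(keys)), keys)
  vb <- va
  va[names(a)[names(a) %in% keys]] <- a[names(a) %in% keys]
  vb[names(b)[names(b) %in% keys]] <- b[names(b) %in% keys]
  list(keys = keys, a = va, b = vb)
}

safe_cor <- function(x, y) {
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
    if (length(x) == 2L && sd(x) > 0 && sd(y) > 0)
      return(list(r = unname(cor(x, y)), p = NA_real_))
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

ngram_counts_of_set <- function(set, order) {
  ct <- count_ngrams(set)
  switch(as.character(order),
    "1" = ct$monogram[ct$monogram > 0L],
    "2" = {
      nz <- which(ct$bigram > 0L, arr.ind = TRUE)
      setNames(as.numeric(ct$bigram[nz]),
               paste(rownames(ct$bigram)[nz[, 1L]],
                     colnames(ct$bigram)[nz[, 2L]]))
    },
    "3" = ct$trigram,
    stop("order must be 1, 2 or 3"))
}

#' Paired n-gram frequency vectors and their correlation
#'
#' Extracts monogram, bigram or trigram frequencies from each set (bigrams
#' and trigrams include NULL-boundary n-grams, as in training), pairs them
#' over the union of n-grams observed in either set (zeros filled in), and
#' reports the Pearson correlation of the within-set-normalised frequencies.
#'
#' @param set_a,set_b Lists of architectures (or `training_corpus` /
#'   `replicate_set` objects).
#' @param order 1 (singletons), 2 (bigrams) or 3 (trigrams).
#' @param intersect_only Restrict to n-grams observed in both sets.
#' @return List: `keys`, `freq_a`, `freq_b` (normalised), `r`, `p_value`,
#'   `n` (number of paired keys).
#' @export
ngram_frequency_vectors <- function(set_a, set_b, order = 1,
                                    intersect_only = FALSE) {
  set_a <- set_as_list(set_a); set_b <- set_as_list(set_b)
  if (!length(set_a) || !length(set_b)) stop("both sets must be nonempty")
  pc <- paired_counts(ngram_counts_of_set(set_a, order),
                      ngram_counts_of_set(set_b, order), intersect_only)
  fa <- pc$a / sum(pc$a); fb <- pc$b / sum(pc$b)
  ct <- safe_cor(fa, fb)
  list(keys = pc$keys, freq_a = fa, freq_b = fb, r = ct$r, p_value = ct$p,
       n = length(pc$keys))
}

cooccurrence_counts_of_set <- function(set) {
  env <- new.env(parent = emptyenv())
  for (da in set) {
    u <- sort(unique(da))
    if (length(u) < 2L) next
    cmb <- utils::combn(u, 2L)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1L, j], cmb[2L, j])
      env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + 1
    }
  }
  keys <- ls(env)
  setNames(vapply(keys, function(k) env[[k]], numeric(1)), keys)
}

#' Pairwise domain co-occurrence counts and their correlation
#'
#' For each unordered pair of distinct domains, counts the number of unique
#' architectures in which both occur anywhere (not necessarily adjacent).
#' Pairs observed in either set form the key universe, zero-filled.
#'
#' @inheritParams ngram_frequency_vectors
#' @return List: `keys` (`"x y"` with `x < y`), `count_a`, `count_b`, `r`,
#'   `p_value`, `n`.
#' @export
pair_cooccurrence <- function(set_a, set_b, intersect_only = FALSE) {
  set_a <- set_as_list(set_a); set_b <- set_as_list(set_b)
  if (!length(set_a) || !length(set_b)) stop("both sets must be nonempty")
  pc <- paired_counts(cooccurrence_counts_of_set(set_a),
                      cooccurrence_counts_of_set(set_b), intersect_only)
  ct <- safe_cor(pc$a, pc$b)
  list(keys = pc$keys, count_a = pc$a, count_b = pc$b, r = ct$r,
       p_value = ct$p, n = length(pc$keys))
}

neighbor_sets <- function(set) {
  env <- new.env(parent = emptyenv())
  add <- function(x, y) {
    cur <- env[[x]]
    if (is.null(cur)) env[[x]] <- y
    else if (!(y %in% cur)) env[[x]] <- c(cur, y)
  }
  for (da in set) {
    n <- length(da)
    if (n < 2L) {
      if (is.null(env[[da[1L]]])) env[[da[1L]]] <- character(0)
      next
    }
    for (i in seq_len(n - 1L)) {
      add(da[i], da[i + 1L]); add(da[i + 1L], da[i])
    }
  }
  env
}

#' Unique adjacent neighbours of each domain
#'
#' A domain promiscuity measure: the number of distinct domains observed
#' immediately adjacent (on either side) to each domain across all unique
#' architectures. NULL termini are not neighbours; a domain adjacent to
#' another copy of itself counts itself as a neighbour.
#'
#' @param set List of architectures.
#' @return Named integer vector (token -> neighbour count), sorted by token.
#' @export
unique_neighbors <- function(set) {
  set <- set_as_list(set)
  if (!length(set)) stop("set must be nonempty")
  env <- neighbor_sets(set)
  keys <- sort(ls(env))
  setNames(vapply(keys, function(k) length(env[[k]]), integer(1)), keys)
}

#' Weighted bigram promiscuity
#'
#' A promiscuity score that discounts promiscuous partners: each distinct
#' adjacent partner `p` of domain `d` contributes weight
#' `1 / (number of distinct partners of p)`, and the score of `d` is the sum
#' of those weights over its partners (computed on unique architectures).
#' A domain whose partners are themselves promiscuous therefore scores lower
#' than one with the same number of dedicated partners. The formula is
#' isolated here so an alternative weighting can be swapped in without
#' touching callers.
#'
#' @param set List of architectures.
#' @param top_n Return the scores of the `top_n` highest-scoring domains
#'   (ties broken lexicographically). `Inf` for all.
#' @return Named numeric vector of scores, decreasing.
#' @export
weighted_bigram_promiscuity <- function(set, top_n = 100) {
  set <- set_as_list(set)
  if (!length(set)) stop("set must be nonempty")
  env <- neighbor_sets(set)
  toks <- sort(ls(env))
  npart <- setNames(vapply(toks, function(k) length(env[[k]]), integer(1)),
                    toks)
  score <- vapply(toks, function(k) {
    ps <- env[[k]]
    if (!length(ps)) return(0)
    sum(1 / npart[ps])
  }, numeric(1))
  ord <- order(-score, toks, method = "radix")
  head(score[ord], if (is.finite(top_n)) top_n else length(score))
}

#' Tandem array statistics per domain superfamily
#'
#' A tandem array is a maximal run of two or more identical adjacent domains
#' within one architecture. For each superfamily, aggregates over all unique
#' architectures: the total number of tandem copies (sum of run lengths),
#' the longest run, the number of arrays, and the mean array length.
#'
#' @param set List of architectures.
#' @return Data frame (`superfamily`, `total`, `max`, `n_arrays`, `mean`)
#'   sorted by decreasing `total`, ties lexicographic. Superfamilies with no
#'   tandem arrays do not appear.
#' @export
tandem_array_stats <- function(set) {
  set <- set_as_list(set)
  if (!length(set)) stop("set must be nonempty")
  runs_tok <- character(0); runs_len <- integer(0)
  for (da in set) {
    r <- rle(da)
    keep <- r$lengths >= 2L
    if (any(keep)) {
      runs_tok <- c(runs_tok, r$values[keep])
      runs_len <- c(runs_len, r$lengths[keep])
    }
  }
  if (!length(runs_tok))
    return(data.frame(superfamily = character(), total = integer(),
                      max = integer(), n_arrays = integer(), mean = numeric(),
                      stringsAsFactors = FALSE))
  total <- tapply(runs_len, runs_tok, sum)
  mx <- tapply(runs_len, runs_tok, max)
  nar <- tapply(runs_len, runs_tok, length)
  out <- data.frame(superfamily = names(total),
                    total = as.integer(total), max = as.integer(mx),
                    n_arrays = as.integer(nar),
                    mean = as.numeric(total) / as.numeric(nar),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$superfamily, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Architecture-probability quantile comparison
#'
#' Scores every architecture in both sets under the first-order model,
#' independently trims the longest `trim_fraction` of each set (longest
#' architectures dominate the left tail of the log-probability distribution;
#' length ties are broken by removing the lower-probability architecture
#' first), and compares matched quantiles (type-7 interpolation) of the two
#' trimmed log-probability distributions.
#'
#' @param model A `first_order_model`.
#' @param set_a,set_b Lists of architectures.
#' @param trim_fraction Fraction of each set removed from the long end
#'   (default 0.01).
#' @return List: `quantiles_a`, `quantiles_b` (matched, on the
#'   log-probability scale), `r`, `p_value`, `n_a`, `n_b` (post-trim sizes),
#'   `n_quantiles`.
#' @export
probability_quantile_comparison <- function(model, set_a, set_b,
                                            trim_fraction = 0.01) {
  set_a <- set_as_list(set_a); set_b <- set_as_list(set_b)
  if (!length(set_a) || !length(set_b)) stop("both sets must be nonempty")
  trim_set <- function(set) {
    lp <- vapply(set, function(da) architecture_log_probability(model, da),
                 numeric(1))
    n_rm <- floor(trim_fraction * length(set))
    if (n_rm >= length(set)) stop("trimming removed every architecture")
    if (n_rm > 0L) {
      drop <- order(-lengths(set), lp, method = "radix")[seq_len(n_rm)]
      lp <- lp[-drop]
    }
    lp
  }
  lpa <- trim_set(set_a); lpb <- trim_set(set_b)
  k <- min(length(lpa), length(lpb))
  probs <- stats::ppoints(k)
  qa <- quantile(lpa, probs = probs, type = 7, names = FALSE)
  qb <- quantile(lpb, probs = probs, type = 7, names = FALSE)
  ct <- safe_cor(qa, qb)
  list(quantiles_a = qa, quantiles_b = qb, r = ct$r, p_value = ct$p,
       n_a = length(lpa), n_b = length(lpb), n_quantiles = k)
}

#' Positional frequencies of accepted gain and loss events
#'
#' Tabulates where accepted events fall within the architecture, by the
#' length of the architecture at the moment the event was proposed
#' (pre-move length). For a pre-move length `n`, gains occupy `n + 1`
#' insertion-site bins (reported 1-based, 1 = before the first domain) and
#' losses occupy `n` position bins. Frequencies are normalised within each
#' (length, kind) stratum.
#'
#' @param traces A `chain_trace` with events, or a list of them (e.g. the
#'   `traces` of [run_replicates()] run with `emit_trace = TRUE`).
#' @param lengths Pre-move architecture lengths to tabulate (default 3:8).
#' @return Data frame (`length`, `kind`, `position`, `count`, `frequency`).
#' @export
event_position_frequencies <- function(traces, lengths = 3:8) {
  if (inherits(traces, "chain_trace")) traces <- list(traces)
  evs <- lapply(traces, function(tr) {
    if (is.null(tr$events)) stop("trace does not retain events; ",
                                 "run with emit_trace = TRUE")
    tr$events
  })
  ev <- do.call(rbind, evs)
  ev <- ev[ev$accepted & ev$kind %in% c("gain", "loss") &
             ev$pre_length %in% lengths, , drop = FALSE]
  rows <- list()
  for (len in lengths) {
    for (kind in c("gain", "loss")) {
      sub <- ev[ev$pre_length == len & ev$kind == kind, , drop = FALSE]
      nbin <- if (kind == "gain") len + 1L else len
      pos <- if (kind == "gain") sub$site + 1L else sub$pos
      cnt <- tabulate(pos, nbins = nbin)
      tot <- sum(cnt)
      rows[[length(rows) + 1L]] <- data.frame(
        length = len, kind = kind, position = seq_len(nbin), count = cnt,
        frequency = if (tot > 0) cnt / tot else rep(NA_real_, nbin),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Full comparison report between two architecture sets
#'
#' Computes the whole battery of order/adjacency statistics on both sets and
#' their Pearson correlations: singleton, bigram and trigram frequencies,
#' pair co-occurrence, unique neighbours, weighted bigram promiscuity (top
#' `top_n` domains of `set_a`), mean tandem array length, and architecture
#' probability quantiles under `model`.
#'
#' @param set_a,set_b Architecture sets (`set_a` is the reference, e.g.
#'   genuine data).
#' @param model A `first_order_model` (for the probability quantile row).
#' @param top_n Number of most promiscuous domains (ranked in `set_a`) for
#'   the weighted-promiscuity row.
#' @param trim_fraction Passed to [probability_quantile_comparison()].
#' @return A `comparison_report`: `table` (data frame `statistic`, `r`,
#'   `p_value`, `n`) plus the underlying paired vectors in `$pairs`.
#' @export
comparison_report <- function(set_a, set_b, model, top_n = 100,
                              trim_fraction = 0.01) {
  set_a <- set_as_list(set_a); set_b <- set_as_list(set_b)
  pairs <- list()
  rows <- list()
  add <- function(name, r, p, n, pair) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = name, r = r, p_value = p, n = n, stringsAsFactors = FALSE)
    pairs[[name]] <<- pair
  }

  for (ord in 1:3) {
    nf <- ngram_frequency_vectors(set_a, set_b, order = ord)
    add(c("singleton_frequency", "bigram_frequency",
          "trigram_frequency")[ord],
        nf$r, nf$p_value, nf$n, list(a = nf$freq_a, b = nf$freq_b))
  }

  co <- pair_cooccurrence(set_a, set_b)
  add("pair_cooccurrence", co$r, co$p_value, co$n,
      list(a = co$count_a, b = co$count_b))

  pc <- paired_counts(unique_neighbors(set_a), unique_neighbors(set_b))
  ct <- safe_cor(pc$a, pc$b)
  add("unique_neighbors", ct$r, ct$p, length(pc$keys),
      list(a = pc$a, b = pc$b))

  wa <- weighted_bigram_promiscuity(set_a, top_n = top_n)
  wb_all <- weighted_bigram_promiscuity(set_b, top_n = Inf)
  toks <- names(wa)
  wb <- setNames(numeric(length(toks)), toks)
  hit <- toks %in% names(wb_all)
  wb[hit] <- wb_all[toks[hit]]
  ct <- safe_cor(unname(wa), unname(wb))
  add("wtd_bigram_promiscuity", ct$r, ct$p, length(toks),
      list(a = wa, b = wb))

  ta <- tandem_array_stats(set_a); tb <- tandem_array_stats(set_b)
  pc <- paired_counts(setNames(ta$mean, ta$superfamily),
                      setNames(tb$mean, tb$superfamily))
  ct <- safe_cor(pc$a, pc$b)
  add("mean_tandem_array_length", ct$r, ct$p, length(pc$keys),
      list(a = pc$a, b = pc$b))

  qq <- probability_quantile_comparison(model, set_a, set_b,
                                        trim_fraction = trim_fraction)
  add("da_probability_quantiles", qq$r, qq$p_value, qq$n_quantiles,
      list(a = qq$quantiles_a, b = qq$quantiles_b))

  structure(list(table = do.call(rbind, rows), pairs = pairs),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("Domain architecture comparison report\n")
  tab <- x$table
  tab$r <- round(tab$r, digits)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats sd
NULL
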