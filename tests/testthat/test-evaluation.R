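test_that("n-gram frequency correlations behave at the extremes", {
  set.seed(12)
  corpus <- unique_architectures(random_corpus(30, c("A", "B", "C")))
  for (ord in 1:3) {
    nf <- ngram_frequency_vectors(corpus, corpus, order = ord)
    expect_equal(nf$r, 1)
    expect_equal(nf$freq_a, nf$freq_b)
  }
  # disjoint singletons over two tokens anti-correlate exactly
  nf <- ngram_frequency_vectors(list("A"), list("B"), order = 1)
  expect_equal(nf$r, -1)
  expect_error(ngram_frequency_vectors(list(), corpus, 1), "nonempty")
})

test_that("statistics are order-invariant and symmetric", {
  set.seed(13)
  corpus <- unique_architectures(random_corpus(40, c("A", "B", "C", "D")))
  other <- unique_architectures(random_corpus(40, c("A", "B", "C", "D")))
  shuffled <- corpus[sample(seq_along(corpus))]
  expect_equal(ngram_frequency_vectors(corpus, other, 2)$r,
               ngram_frequency_vectors(shuffled, other, 2)$r)
  expect_equal(pair_cooccurrence(corpus, other)$r,
               pair_cooccurrence(other, corpus)$r)
  expect_identical(unique_neighbors(corpus), unique_neighbors(shuffled))
})

test_that("pair co-occurrence counts architectures containing both domains", {
  co <- pair_cooccurrence(list(c("A", "B", "A")), list(c("A", "B", "A")))
  expect_equal(unname(co$count_a["A B"]), 1)

  # tokens never co-resident score zero when zero-filled against the union
  co2 <- pair_cooccurrence(list(c("A", "B")), list(c("A", "C")))
  expect_equal(unname(co2$count_a["A C"]), 0)
  expect_equal(unname(co2$count_b["A B"]), 0)

  # brute-force oracle over all token pairs on a toy corpus
  toy <- list(c("A", "B", "A"), c("B", "C"), c("A", "C", "B", "C"), "D")
  counts <- cooccurrence_oracle(toy)
  co3 <- pair_cooccurrence(toy, toy)
  expect_equal(co3$count_a[names(counts)], counts)
})

test_that("unique neighbour counts include self-adjacency, exclude termini", {
  nb <- unique_neighbors(list(c("A", "B"), c("B", "C")))
  expect_equal(unname(nb["B"]), 2L)
  expect_equal(unname(nb["A"]), 1L)
  nb2 <- unique_neighbors(list(c("A", "A")))
  expect_equal(unname(nb2["A"]), 1L)
  # single-domain architectures contribute tokens with zero neighbours
  nb3 <- unique_neighbors(list("A"))
  expect_equal(unname(nb3["A"]), 0L)

  set.seed(14)
  corpus <- unique_architectures(random_corpus(50, sprintf("T%d", 1:6)))
  expect_identical(unique_neighbors(corpus), neighbor_oracle(corpus))
})

test_that("weighted bigram promiscuity follows the partner-discount formula", {
  # spreadsheet-style recomputation: partners and their degrees by hand.
  # corpus: [A,B], [A,C], [B,C] -> partners A:{B,C} B:{A,C} C:{A,B}, all
  # degree 2 -> every score = 1/2 + 1/2 = 1
  w <- weighted_bigram_promiscuity(list(c("A", "B"), c("A", "C"),
                                        c("B", "C")))
  expect_true(all(abs(w - 1) < 1e-12))

  # hub-and-spoke: H touches A, B, C (each degree 1 -> score 3);
  # spokes each have only partner H (degree 3 -> score 1/3)
  hub <- list(c("H", "A"), c("H", "B"), c("H", "C"))
  w2 <- weighted_bigram_promiscuity(hub)
  expect_equal(unname(w2["H"]), 3)
  expect_equal(unname(w2["A"]), 1 / 3)
  expect_identical(names(w2)[1], "H")
  # two statistically identical tokens score equally, ties lexicographic
  expect_equal(unname(w2["A"]), unname(w2["B"]))
  expect_identical(names(w2), c("H", "A", "B", "C"))
})

test_that("tandem arrays are maximal runs of length at least two", {
  ta <- tandem_array_stats(list(c("A", "A", "A", "B")))
  expect_equal(ta$superfamily, "A")
  expect_equal(ta$total, 3L)
  expect_equal(ta$max, 3L)
  expect_equal(ta$mean, 3)

  expect_equal(nrow(tandem_array_stats(list(c("A", "B", "A")))), 0L)

  set.seed(15)
  corpus <- random_corpus(60, c("A", "B"), max_len = 8)
  expect_equal(tandem_array_stats(corpus), tandem_oracle(corpus))
})

test_that("probability quantile comparison is exact on identical sets", {
  set.seed(16)
  corpus <- unique_architectures(random_corpus(80, c("A", "B", "C")))
  m <- build_model(count_ngrams(corpus), k = "default")
  qq <- probability_quantile_comparison(m, corpus, corpus)
  expect_equal(qq$r, 1)
  expect_equal(qq$quantiles_a, qq$quantiles_b)

  # without extreme lengths, trimming changes little
  qq0 <- probability_quantile_comparison(m, corpus, corpus,
                                         trim_fraction = 0)
  expect_equal(qq0$r, 1)
  expect_equal(qq$n_a, length(corpus) - floor(0.01 * length(corpus)))
  expect_error(probability_quantile_comparison(m, corpus, corpus,
                                               trim_fraction = 1),
               "trimming")
})

test_that("event positions are binned by pre-move length and normalised", {
  events <- data.frame(
    iteration = 1:4,
    kind = c("gain", "gain", "loss", "loss"),
    site = c(0L, 3L, NA, NA),
    pos = c(NA, NA, 1L, 3L),
    token = c("A", "B", NA, NA),
    pre_length = c(3L, 3L, 3L, 3L),
    log_ratio = 0,
    accepted = TRUE,
    stringsAsFactors = FALSE
  )
  tr <- structure(list(sampled_lengths = NULL, tallies = NULL,
                       events = events, config = NULL, start = NULL),
                  class = "chain_trace")
  epf <- event_position_frequencies(tr, lengths = 3)
  g <- epf[epf$kind == "gain", ]
  expect_equal(g$count, c(1L, 0L, 0L, 1L))      # sites 0 and 3 -> bins 1, 4
  l <- epf[epf$kind == "loss", ]
  expect_equal(l$count, c(1L, 0L, 1L))
  expect_equal(sum(g$frequency), 1)
  expect_equal(sum(l$frequency), 1)
})

test_that("the shrink factor separates converged from divergent chains", {
  # identical chains: no between-chain variance, PSRF ~ 1
  set.seed(17)
  x <- cumsum(rnorm(400))
  gr <- gelman_rubin(cbind(x, x, x))
  expect_equal(gr$B, 0)
  expect_equal(gr$psrf, 1, tolerance = 0.01)

  # chains around means 3 and 30 are flagrantly unconverged
  a <- rnorm(400, 3); b <- rnorm(400, 30)
  gr2 <- gelman_rubin(cbind(a, b))
  expect_gt(gr2$psrf, 5)
  expect_false(gr2$converged)

  # agreement with an independent direct recomputation on fixed arrays
  set.seed(18)
  chains <- matrix(rnorm(300 * 4, mean = rep(c(0, .2, .1, -.1), each = 300)),
                   ncol = 4)
  gr3 <- gelman_rubin(chains, discard_first = 0.5)
  expect_equal(gr3$psrf, psrf_oracle(chains[151:300, ]), tolerance = 1e-10)

  expect_error(gelman_rubin(cbind(a)), "at least 2")
  expect_error(gelman_rubin(list(a, b[1:100])), "same length")
})

test_that("a full comparison report covers every statistic", {
  set.seed(19)
  corpus <- unique_architectures(random_corpus(60, sprintf("T%d", 1:5),
                                               max_len = 7))
  m <- build_model(count_ngrams(corpus), k = "default")
  rep_ <- comparison_report(corpus, corpus, m)
  expect_setequal(rep_$table$statistic,
                  c("singleton_frequency", "bigram_frequency",
                    "trigram_frequency", "pair_cooccurrence",
                    "unique_neighbors", "wtd_bigram_promiscuity",
                    "mean_tandem_array_length", "da_probability_quantiles"))
  expect_true(all(abs(rep_$table$r - 1) < 1e-12 | is.na(rep_$table$r)))
})
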