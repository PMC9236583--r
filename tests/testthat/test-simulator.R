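test_that("event types and gain moves are proposed uniformly", {
  m <- toy_trained_model()              # N_D = 3
  cfg <- simulation_config(proposal_mode = "paper")
  state <- c("A", "B")
  set.seed(1)
  n_prop <- 20000
  gains <- 0L
  cells <- integer(9)                   # 3 sites x 3 tokens
  for (i in seq_len(n_prop)) {
    pr <- propose(state, m, cfg)
    if (pr$event$kind == "gain") {
      gains <- gains + 1L
      cell <- pr$event$site * 3L + match(pr$event$token, m$alphabet)
      cells[cell] <- cells[cell] + 1L
    }
  }
  # gain fraction 1 - 1/N_D within 3 sigma binomial error
  p <- 1 - 1 / 3
  expect_lt(abs(gains / n_prop - p), 3 * sqrt(p * (1 - p) / n_prop))
  # site x token uniformity among gains
  expect_gt(chisq.test(cells)$p.value, 0.01)
})

test_that("acceptance probabilities clamp at one and invert for paired moves", {
  m <- toy_trained_model(k = 0.3)
  state <- c("A", "B")
  ev_gain <- list(kind = "gain", site = 1L, pos = NA_integer_, token = "C",
                  vetoed = FALSE)
  cand <- c("A", "C", "B")
  a <- accept_probability(m, state, cand, ev_gain, mode = "paper")
  r <- insertion_ratio(m, state, 1, "C")
  expect_equal(a, min(1, r))

  # reverse deletion: ratios are exact reciprocals, and in exact-hastings
  # mode the two proposal corrections cancel
  ev_loss <- list(kind = "loss", site = NA_integer_, pos = 2L,
                  token = NA_character_, vetoed = FALSE)
  r_del <- deletion_ratio(m, cand, 2)
  expect_equal(r * r_del, 1, tolerance = 1e-12)
  nd <- length(m$alphabet)
  g <- nd / (nd + 1)
  qcorr <- (1 - g) * nd / g
  expect_equal(qcorr, 1)               # symmetric proposal law: no residual

  expect_error(accept_probability(m, state, c("A", "B", "C", "A"), ev_gain),
               "not adjacent")
})

test_that("single-domain deletions are vetoed and chains never go extinct", {
  m <- toy_trained_model()
  cfg <- simulation_config(T = 2000, seed = 5, trace_every = 10,
                           emit_trace = TRUE, start = "A")
  res <- run_chain(m, cfg)
  expect_gte(min(res$trace$sampled_lengths$length), 1L)
  expect_gte(length(res$final), 1L)
  vetoes <- res$trace$events[res$trace$events$kind == "vetoed_loss", ]
  expect_gt(nrow(vetoes), 0L)
  expect_true(all(vetoes$pre_length == 1L))
  expect_true(all(!vetoes$accepted))
  expect_equal(nrow(vetoes), unname(res$trace$tallies["vetoed_loss"]))
})

test_that("T = 0 returns the start and seeded runs are bit-reproducible", {
  m <- toy_trained_model()
  cfg0 <- simulation_config(T = 0, seed = 3, start = c("B", "A"))
  expect_identical(run_chain(m, cfg0)$final, c("B", "A"))

  cfg <- simulation_config(T = 1000, seed = 77, emit_trace = TRUE)
  r1 <- run_chain(m, cfg)
  r2 <- run_chain(m, cfg)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$trace$events, r2$trace$events)
})

test_that("the compiled and pure-R engines replay the same chain", {
  m <- toy_trained_model(k = 0.15)
  for (mode in c("paper", "symmetric", "exact-hastings")) {
    cfg <- simulation_config(T = 400, seed = 13, proposal_mode = mode,
                             trace_every = 50, emit_trace = TRUE,
                             start = "A")
    a <- run_chain(m, cfg, engine = "cpp")
    b <- run_chain(m, cfg, engine = "r")
    expect_identical(a$final, b$final)
    expect_equal(a$trace$tallies, b$trace$tallies)
    expect_equal(a$trace$sampled_lengths, b$trace$sampled_lengths)
    ea <- a$trace$events; eb <- b$trace$events
    rownames(ea) <- rownames(eb) <- NULL
    expect_equal(ea$kind, eb$kind)
    expect_equal(ea$site, eb$site)
    expect_equal(ea$pos, eb$pos)
    expect_equal(ea$accepted, eb$accepted)
    expect_equal(ea$log_ratio, eb$log_ratio, tolerance = 1e-12)
  }
})

test_that("forbidden adjacencies are never accepted", {
  m0 <- build_model(count_ngrams(list(c("A", "B"), c("B", "A"), "A", "B")),
                    k = 0)
  # (A, A) never observed: any gain creating it has ratio 0
  expect_identical(insertion_ratio(m0, c("A", "B"), 0, "A"), 0)
  cfg <- simulation_config(T = 3000, seed = 2, emit_trace = TRUE,
                           start = "A")
  res <- run_chain(m0, cfg, allow_reducible = TRUE)
  ev <- res$trace$events
  zero_ratio <- ev$log_ratio == -Inf & !is.na(ev$log_ratio)
  expect_true(any(zero_ratio))
  expect_true(all(!ev$accepted[zero_ratio]))
})

test_that("replicates are independent, seeded and summarised", {
  m <- toy_trained_model()
  cfg <- simulation_config(T = 0, seed = 8, replicates = 10)
  reps <- run_replicates(m, cfg)
  expect_equal(length(reps$finals), 10L)
  expect_true(all(lengths(reps$finals) == 1L))

  cfg2 <- simulation_config(T = 500, seed = 8, replicates = 5)
  a <- run_replicates(m, cfg2)
  b <- run_replicates(m, cfg2)
  expect_identical(a$finals, b$finals)
  expect_identical(a$seeds, b$seeds)

  # match-corpus resolves to the number of unique training DAs
  cfg3 <- simulation_config(T = 0, seed = 1, replicates = "match-corpus")
  expect_equal(length(run_replicates(m, cfg3)$finals), m$n_unique_das)

  # monogram-weighted starts only ever draw observed tokens
  cfg4 <- simulation_config(T = 0, seed = 4, replicates = 50,
                            start_weighting = "monogram")
  starts <- unlist(run_replicates(m, cfg4)$finals)
  expect_true(all(starts %in% names(which(m$counts$monogram > 0))))
})

test_that("acceptance rates equilibrate with gains balancing losses", {
  fx <- make_paperlike_fixture("small")
  tm <- build_model(count_ngrams(fx$corpus))
  res <- run_chain(tm, simulation_config(T = 2e5, seed = 6))
  tl <- res$trace$tallies
  # at stationarity accepted gains and losses differ only by the net change
  # in length over the run
  expect_lt(abs(tl["accepted_gain"] - tl["accepted_loss"]),
            0.1 * tl["accepted_gain"])
  sl <- res$trace$sampled_lengths$length
  expect_gt(mean(sl), 1)
  expect_true(is.finite(mean(sl)))
})

test_that("the stationary distribution matches the first-order probabilities", {
  # two-token ground truth; exact-hastings sampling must reproduce the
  # model's own architecture distribution over the 14 shortest states
  spec <- generator_spec(alphabet_size = 2, transition_sparsity = 0,
                         termination_strength = 0.45, corpus_size = 5,
                         seed = 5)
  gt <- sample_ground_truth(spec)
  burn <- run_chain(gt, simulation_config(
    T = 5e4, seed = 17, proposal_mode = "exact-hastings", trace_every = 1e4))
  res <- run_chain(gt, simulation_config(
    start = burn$final, T = 3e5, seed = NA,
    proposal_mode = "exact-hastings", trace_every = 1e4), tally_max_len = 3)
  tal <- res$trace$state_tally
  lp <- vapply(enumerate_short_architectures(gt$alphabet, 3),
               function(da) architecture_log_probability(gt, da), numeric(1))
  p_theory <- exp(lp) / sum(exp(lp))
  tv <- 0.5 * sum(abs(tal / sum(tal) - p_theory))
  expect_lt(tv, 0.05)
})
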