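# Metropolis-Hastings simulation of domain architecture evolution.
#
# At every iteration one move is proposed: a gain (insert one domain at one
# of the n + 1 sites, token uniform over the alphabet) or a loss (delete one
# of the n domains). Because a length-n architecture has (n + 1) * N_D gain
# neighbours but only n loss neighbours, gains are proposed with roughly
# N_D : 1 odds so that all adjacent states are proposed with comparable
# probability. A proposal is accepted with min(1, p(t)/p(s)) where the ratio
# comes from the cancelled first-order forms (insertion_ratio /
# deletion_ratio). Deletions that would empty the architecture are vetoed:
# extinction is forbidden.

#' Simulation configuration
#'
#' @param start Either a character vector (the starting architecture) or
#'   `"random-single-domain"` to draw a single-domain start per chain.
#' @param T Number of proposed state transitions (iterations), >= 0.
#' @param replicates Number of independent chains, or `"match-corpus"` to use
#'   the number of unique training DAs recorded on the model.
#' @param k Pseudocount override (`"default"` = `1/N_D`), or `NULL` to use
#'   the model as supplied.
#' @param seed Integer seed, or `NA` to continue the current RNG stream.
#' @param proposal_mode `"paper"` proposes a gain iff a uniform draw exceeds
#'   `1/N_D` (gain odds `N_D - 1 : 1`); `"symmetric"` uses gain odds
#'   `N_D : 1`, under which the proposal probabilities of a move and its
#'   reverse are equal; `"exact-hastings"` uses the symmetric proposal and
#'   additionally folds the (generally unity) proposal ratio into the
#'   acceptance probability, so the stationary distribution is exactly
#'   proportional to the first-order architecture probability. The two gain
#'   odds differ by O(1/N_D^2) per step.
#' @param gain_loss_bias Multiplies the gain odds (default 1). Values other
#'   than 1 break the uniform-proposal property and hence the convergence
#'   guarantee; exposed for experimentation.
#' @param trace_every Sampling interval for the architecture-length trace
#'   (default 100, the cadence used for convergence diagnostics).
#' @param emit_trace Event-log retention: `FALSE` (none), `TRUE` (every
#'   iteration; memory: one row per iteration) or `"accepted"` (accepted
#'   moves only, the cheap option for event-position statistics).
#' @param veto_consumes_iteration If `TRUE` (default) a vetoed single-domain
#'   deletion counts as one of the `T` iterations; if `FALSE` it is redrawn.
#' @param start_weighting For random starts: `"uniform"` over the alphabet
#'   (default) or `"monogram"` (weighted by training monogram counts).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(start = "random-single-domain", T = 10000L,
                              replicates = 1L, k = NULL, seed = 1L,
                              proposal_mode = c("paper", "symmetric",
                                                "exact-hastings"),
                              gain_loss_bias = 1, trace_every = 100L,
                              emit_trace = FALSE,
                              veto_consumes_iteration = TRUE,
                              start_weighting = c("uniform", "monogram")) {
  proposal_mode <- match.arg(proposal_mode)
  start_weighting <- match.arg(start_weighting)
  if (!identical(start, "random-single-domain")) assert_architecture(start)
  if (T < 0) stop("T must be >= 0")
  if (!identical(replicates, "match-corpus") && replicates < 1)
    stop("replicates must be >= 1")
  if (trace_every < 1) stop("trace_every must be >= 1")
  if (gain_loss_bias <= 0) stop("gain_loss_bias must be positive")
  if (!isTRUE(emit_trace) && !isFALSE(emit_trace) &&
      !identical(emit_trace, "accepted"))
    stop("emit_trace must be TRUE, FALSE or \"accepted\"")
  structure(
    list(start = start, T = as.integer(T), replicates = replicates, k = k,
         seed = seed, proposal_mode = proposal_mode,
         gain_loss_bias = gain_loss_bias,
         trace_every = as.integer(trace_every), emit_trace = emit_trace,
         veto_consumes_iteration = veto_consumes_iteration,
         start_weighting = start_weighting),
    class = "simulation_config"
  )
}

mode_code <- function(mode) {
  match(mode, c("paper", "symmetric", "exact-hastings")) - 1L
}

gain_probability <- function(mode, n_d, bias = 1) {
  odds <- (if (mode == "paper") n_d - 1 else n_d) * bias
  odds / (1 + odds)
}

#' Propose one gain or loss move
#'
#' Draws the event type, site and (for gains) token for a single proposal,
#' consuming the current RNG stream. Exposed mainly for testing and for the
#' pure-R reference engine; [run_chain()] uses the compiled loop.
#'
#' @param state Current architecture (character vector).
#' @param model A `first_order_model`.
#' @param config A [simulation_config()] (proposal mode and bias are used).
#' @return A list with `event` (list: `kind` = `"gain"`/`"loss"`, `site` =
#'   0-based insertion site for gains, `pos` = 1-based position for losses,
#'   `token` for gains, `vetoed` flag) and `candidate` (the proposed
#'   architecture, or the unchanged state for a vetoed deletion).
#' @export
propose <- function(state, model, config = simulation_config()) {
  assert_architecture(state, model$alphabet)
  n <- length(state)
  nd <- length(model$alphabet)
  g <- gain_probability(config$proposal_mode, nd, config$gain_loss_bias)
  u1 <- runif(1)
  if (u1 > 1 - g) {                      # gain
    site <- min(n, floor(runif(1) * (n + 1)))
    tok <- model$alphabet[min(nd - 1, floor(runif(1) * nd)) + 1L]
    candidate <- append(state, tok, after = site)
    event <- list(kind = "gain", site = as.integer(site), pos = NA_integer_,
                  token = tok, vetoed = FALSE)
  } else {                               # loss
    pos <- min(n - 1, floor(runif(1) * n)) + 1L
    if (n == 1L) {
      event <- list(kind = "loss", site = NA_integer_, pos = pos,
                    token = NA_character_, vetoed = TRUE)
      candidate <- state
    } else {
      candidate <- state[-pos]
      event <- list(kind = "loss", site = NA_integer_, pos = pos,
                    token = NA_character_, vetoed = FALSE)
    }
  }
  list(event = event, candidate = candidate)
}

#' Metropolis-Hastings acceptance probability of a proposed move
#'
#' @param model A `first_order_model`.
#' @param state Current architecture.
#' @param candidate Proposed architecture (must be adjacent to `state` via
#'   `event`).
#' @param event Event list as returned by [propose()].
#' @param mode Proposal mode (see [simulation_config()]); in
#'   `"exact-hastings"` the proposal ratio `q(t -> s) / q(s -> t)` is folded
#'   in (it equals 1 under the symmetric proposal law).
#' @param gain_loss_bias Gain-odds multiplier used by the proposal law.
#' @return Acceptance probability in `[0, 1]` (0 for a vetoed move).
#' @export
accept_probability <- function(model, state, candidate, event,
                               mode = "paper", gain_loss_bias = 1) {
  if (isTRUE(event$vetoed)) return(0)
  nd <- length(model$alphabet)
  if (event$kind == "gain") {
    if (length(candidate) != length(state) + 1L)
      stop("candidate is not adjacent to state via the given gain event")
    ratio <- insertion_ratio(model, state, event$site, event$token)
  } else {
    if (length(candidate) != length(state) - 1L)
      stop("candidate is not adjacent to state via the given loss event")
    ratio <- deletion_ratio(model, state, event$pos)
  }
  if (mode == "exact-hastings" && is.finite(ratio)) {
    g <- gain_probability(mode, nd, gain_loss_bias)
    qcorr <- (1 - g) * nd / g
    ratio <- ratio * (if (event$kind == "gain") qcorr else 1 / qcorr)
  }
  min(1, ratio)
}

#' One propose/accept cycle
#'
#' @inheritParams propose
#' @return A list with `state` (the post-move architecture), `event`
#'   (augmented with `ratio` and `accepted`), and `vetoed`.
#' @export
step <- function(state, model, config = simulation_config()) {
  pr <- propose(state, model, config)
  ev <- pr$event
  if (ev$vetoed) {
    ev$ratio <- NA_real_; ev$accepted <- FALSE
    return(list(state = state, event = ev, vetoed = TRUE))
  }
  if (ev$kind == "gain") {
    ratio <- insertion_ratio(model, state, ev$site, ev$token)
  } else {
    ratio <- deletion_ratio(model, state, ev$pos)
  }
  if (config$proposal_mode == "exact-hastings" && is.finite(ratio)) {
    g <- gain_probability(config$proposal_mode, length(model$alphabet),
                          config$gain_loss_bias)
    qcorr <- (1 - g) * length(model$alphabet) / g
    ratio <- ratio * (if (ev$kind == "gain") qcorr else 1 / qcorr)
  }
  u <- runif(1)
  accepted <- ratio >= 1 || u < ratio
  ev$ratio <- ratio; ev$accepted <- accepted
  list(state = if (accepted) pr$candidate else state, event = ev,
       vetoed = FALSE)
}

check_irreducible <- function(model, allow_reducible) {
  nd <- length(model$alphabet)
  p <- model$prob
  p[nd + 1L, nd + 1L] <- NA               # structurally zero, not a gap
  if (any(p == 0, na.rm = TRUE) && !allow_reducible)
    stop("model has zero-probability transitions (k = 0 and unseen bigrams):",
         " the chain is not irreducible. Use a positive pseudocount or",
         " allow_reducible = TRUE.")
}

resolve_start <- function(config, model) {
  if (!identical(config$start, "random-single-domain")) {
    assert_architecture(config$start, model$alphabet)
    return(config$start)
  }
  nd <- length(model$alphabet)
  u <- runif(1)
  if (config$start_weighting == "monogram") {
    if (is.null(model$counts))
      stop("monogram-weighted starts need a count-backed model")
    w <- model$counts$monogram / sum(model$counts$monogram)
    model$alphabet[which(u <= cumsum(w))[1]]
  } else {
    model$alphabet[min(nd - 1, floor(u * nd)) + 1L]
  }
}

resolve_model_k <- function(model, config) {
  if (is.null(config$k)) return(model)
  k <- resolve_pseudocount(config$k, length(model$alphabet))
  if (isTRUE(all.equal(k, model$k))) return(model)
  if (is.null(model$counts))
    stop("cannot re-smooth a model without count tables")
  build_model(model$counts, k = k)
}

#' Run one Metropolis-Hastings chain
#'
#' @param model A `first_order_model`.
#' @param config A [simulation_config()].
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (pure-R reference
#'   implementation via [step()]; identical draw sequence, so both engines
#'   produce the same chain from the same seed).
#' @param allow_reducible Run even if the model has zero-probability
#'   transitions (the chain then cannot leave the support of the model).
#' @param tally_max_len If positive, additionally tally the visited state at
#'   every iteration whenever its length is `<= tally_max_len` (compiled
#'   engine only); used for stationary-distribution checks against
#'   [enumerate_short_architectures()].
#' @return A list with `final` (the architecture after `T` iterations) and
#'   `trace`, a `chain_trace`: `sampled_lengths` (data frame `iteration`,
#'   `length` at the `trace_every` cadence), `tallies` (proposed/accepted
#'   gains and losses, vetoed deletions), `events` (data frame when
#'   `emit_trace`; `kind` is `"gain"`, `"loss"` or `"vetoed_loss"`, gain
#'   sites 0-based, loss positions 1-based, `pre_length` the pre-move
#'   length), `state_tally` (when `tally_max_len > 0`), and `start`.
#' @export
run_chain <- function(model, config = simulation_config(), engine = "cpp",
                      allow_reducible = FALSE, tally_max_len = 0L) {
  stopifnot(inherits(model, "first_order_model"),
            inherits(config, "simulation_config"))
  model <- resolve_model_k(model, config)
  check_irreducible(model, allow_reducible)
  if (!is.na(config$seed)) set.seed(config$seed)
  start <- resolve_start(config, model)
  nd <- length(model$alphabet)

  emit_code <- if (isTRUE(config$emit_trace)) 1L
               else if (identical(config$emit_trace, "accepted")) 2L else 0L
  if (engine == "cpp") {
    res <- cpp_run_chain(model$logp, match(start, model$alphabet) - 1L,
                         config$T, nd, mode_code(config$proposal_mode),
                         config$gain_loss_bias, config$trace_every,
                         emit_code, config$veto_consumes_iteration,
                         as.integer(tally_max_len))
    final <- model$alphabet[res$final + 1L]
    events <- NULL
    if (emit_code > 0L) {
      ev <- res$events
      events <- data.frame(
        iteration = ev$iteration,
        kind = c("gain", "loss", "vetoed_loss")[ev$kind + 1L],
        site = ifelse(ev$kind == 0L, ev$site, NA_integer_),
        pos = ifelse(ev$kind >= 1L, ev$site + 1L, NA_integer_),
        token = ifelse(is.na(ev$token), NA_character_,
                       model$alphabet[ev$token + 1L]),
        pre_length = ev$pre_length,
        log_ratio = ev$log_ratio,
        accepted = ev$accepted == 1L,
        stringsAsFactors = FALSE
      )
    }
    trace <- new_chain_trace(
      data.frame(iteration = res$sample_iteration,
                 length = res$sample_length),
      c(proposed_gain = res$proposed_gain, proposed_loss = res$proposed_loss,
        accepted_gain = res$accepted_gain, accepted_loss = res$accepted_loss,
        vetoed_loss = res$vetoed_loss),
      events, config, start)
    if (tally_max_len > 0)
      trace$state_tally <- setNames(
        res$tally,
        vapply(enumerate_short_architectures(model$alphabet, tally_max_len),
               paste, character(1), collapse = " "))
    return(list(final = final, trace = trace))
  }

  if (engine != "r") stop("unknown engine: ", engine)
  run_chain_r(model, config, start)
}

# Pure-R reference engine; consumes the same RNG draws as the compiled loop.
run_chain_r <- function(model, config, start) {
  state <- start
  emit <- !isFALSE(config$emit_trace)
  accepted_only <- identical(config$emit_trace, "accepted")
  tallies <- c(proposed_gain = 0, proposed_loss = 0, accepted_gain = 0,
               accepted_loss = 0, vetoed_loss = 0)
  samples <- list()
  events <- if (emit) vector("list", config$T) else NULL
  t <- 0L
  while (t < config$T) {
    t <- t + 1L
    pre_n <- length(state)
    st <- step(state, model, config)
    if (st$vetoed) {
      tallies["vetoed_loss"] <- tallies["vetoed_loss"] + 1
      if (!config$veto_consumes_iteration) { t <- t - 1L; next }
    } else {
      kindkey <- paste0("proposed_", st$event$kind)
      tallies[kindkey] <- tallies[kindkey] + 1
      if (st$event$accepted) {
        acckey <- paste0("accepted_", st$event$kind)
        tallies[acckey] <- tallies[acckey] + 1
      }
    }
    state <- st$state
    if (emit && !(accepted_only && (st$vetoed || !isTRUE(st$event$accepted)))) {
      ev <- st$event
      events[[t]] <- data.frame(
        iteration = t,
        kind = if (st$vetoed) "vetoed_loss" else ev$kind,
        site = if (identical(ev$kind, "gain")) ev$site else NA_integer_,
        pos = ev$pos,
        token = if (is.null(ev$token)) NA_character_ else ev$token,
        pre_length = pre_n,
        log_ratio = if (is.na(ev$ratio)) NA_real_ else log(ev$ratio),
        accepted = isTRUE(ev$accepted),
        stringsAsFactors = FALSE
      )
    }
    if (t %% config$trace_every == 0L)
      samples[[length(samples) + 1L]] <- c(t, length(state))
  }
  samp <- if (length(samples)) {
    m <- do.call(rbind, samples)
    data.frame(iteration = m[, 1L], length = m[, 2L])
  } else data.frame(iteration = integer(), length = integer())
  ev_df <- if (emit)
    do.call(rbind, events[!vapply(events, is.null, logical(1))]) else NULL
  list(final = state,
       trace = new_chain_trace(samp, tallies, ev_df, config, start))
}

new_chain_trace <- function(sampled_lengths, tallies, events, config, start) {
  structure(list(sampled_lengths = sampled_lengths, tallies = tallies,
                 events = events, config = config, start = start),
            class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  tl <- x$tallies
  cat("Chain trace: T =", x$config$T, "iterations\n")
  cat(sprintf("  gains: %d/%d accepted | losses: %d/%d accepted | vetoed: %d\n",
              as.integer(tl["accepted_gain"]), as.integer(tl["proposed_gain"]),
              as.integer(tl["accepted_loss"]), as.integer(tl["proposed_loss"]),
              as.integer(tl["vetoed_loss"])))
  if (nrow(x$sampled_lengths))
    cat("  sampled lengths: mean", round(mean(x$sampled_lengths$length), 2),
        "over", nrow(x$sampled_lengths), "samples\n")
  invisible(x)
}

#' Enumerate all architectures up to a maximum length
#'
#' Order matches the `state_tally` layout of [run_chain()]: by length, then
#' lexicographically by alphabet index within each length.
#'
#' @param alphabet Character vector of tokens.
#' @param max_len Maximum architecture length.
#' @return List of architectures (character vectors).
#' @export
enumerate_short_architectures <- function(alphabet, max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rev(replicate(len, seq_along(alphabet),
                                    simplify = FALSE)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
    grid <- grid[, rev(seq_len(len)), drop = FALSE]
    for (i in seq_len(nrow(grid)))
      out[[length(out) + 1L]] <- alphabet[as.integer(grid[i, ])]
  }
  out
}

#' Run a suite of independent replicate chains
#'
#' Each replicate runs its own chain from its own start with an independent
#' seed derived from the configuration seed, so any single replicate can be
#' re-run in isolation.
#'
#' @param model A `first_order_model`.
#' @param config A [simulation_config()]; `replicates = "match-corpus"` uses
#'   the number of unique training DAs recorded on the model.
#' @param keep_traces Retain each replicate's `chain_trace` (defaults to
#'   whether `config$emit_trace` requests an event log).
#' @param allow_reducible Passed to [run_chain()].
#' @return A `replicate_set`: `finals` (list of final architectures),
#'   `summary` (final-length distribution, aggregated tallies, acceptance
#'   rates), `seeds` (per-replicate seeds) and optionally `traces`.
#' @export
run_replicates <- function(model, config,
                           keep_traces = !isFALSE(config$emit_trace),
                           allow_reducible = FALSE) {
  n_rep <- config$replicates
  if (identical(n_rep, "match-corpus")) {
    n_rep <- model$n_unique_das
    if (is.na(n_rep))
      stop("\"match-corpus\" needs a model trained from a corpus")
  }
  model <- resolve_model_k(model, config)
  if (!is.na(config$seed)) set.seed(config$seed)
  seeds <- sample.int(2147483646L, n_rep)
  finals <- vector("list", n_rep)
  traces <- if (keep_traces) vector("list", n_rep) else NULL
  tallies <- c(proposed_gain = 0, proposed_loss = 0, accepted_gain = 0,
               accepted_loss = 0, vetoed_loss = 0)
  for (r in seq_len(n_rep)) {
    cfg_r <- config
    cfg_r$seed <- seeds[r]
    cfg_r$replicates <- 1L
    res <- run_chain(model, cfg_r, allow_reducible = allow_reducible)
    finals[[r]] <- res$final
    tallies <- tallies + res$trace$tallies
    if (keep_traces) traces[[r]] <- res$trace
  }
  lens <- lengths(finals)
  summary <- list(
    n_replicates = n_rep, T = config$T,
    final_lengths = lens,
    mean_final_length = mean(lens), median_final_length = median(lens),
    tallies = tallies,
    gain_acceptance_rate = unname(tallies["accepted_gain"] /
                                    max(1, tallies["proposed_gain"])),
    loss_acceptance_rate = unname(tallies["accepted_loss"] /
                                    max(1, tallies["proposed_loss"]))
  )
  structure(list(finals = finals, summary = summary, seeds = seeds,
                 traces = traces),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  s <- x$summary
  cat("Replicate set:", s$n_replicates, "chains, T =", s$T, "\n")
  cat("  final DA length: mean", round(s$mean_final_length, 2),
      "median", s$median_final_length, "\n")
  cat("  acceptance: gains", signif(s$gain_acceptance_rate, 3),
      "losses", signif(s$loss_acceptance_rate, 3), "\n")
  invisible(x)
}
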