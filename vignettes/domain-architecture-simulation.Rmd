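---
title: "Simulating domain architecture evolution with darchsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating domain architecture evolution with darchsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darchsim)
```

## The model

Multidomain proteins are mosaics of independently folding modules
(domains). Ignoring amino-acid sequence, a protein is summarised by its
*domain architecture* (DA): the ordered N- to C-terminal list of domain
superfamily tokens. Architectures evolve by gain and loss of single domains,
but only a tiny fraction of possible domain combinations is ever realised —
domain order and adjacency are under strong constraint. darchsim simulates
DA evolution in a way that respects those constraints by making them
*data-driven*: the chance of any particular gain or loss is derived from
bigram (adjacent-pair) statistics of a training corpus of genuine
architectures.

The state space is the set of non-empty architectures. A state of length
$n$ is adjacent to $n + (n+1)N_D$ states ($N_D$ = alphabet size): $n$
deletions and $(n+1)N_D$ insertions; single-domain states cannot lose their
only domain (extinction is forbidden), leaving $2N_D$ neighbours. The
probability of an architecture $d_1 \dots d_n$ is approximated to first
order, with a NULL sentinel marking the termini:

$$ p(d_1\dots d_n) \approx p(d_1\,|\,\varnothing)\;
   p(d_2\,|\,d_1)\cdots p(\varnothing\,|\,d_n), $$

i.e. $n+1$ conditional factors. Conditionals are estimated from bigram
counts over the *unique* training architectures (deduplication removes the
over-representation of bigrams caused by gene duplication rather than
domain-level change), with add-$k$ smoothing:

$$ p(y\,|\,x) = \frac{C(x,y) + k}{\sum_{y'} C(x,y') + k\,
   |\mathrm{cont}(x)|}. $$

The continuation set of every context is the alphabet plus NULL, except
that the NULL context excludes the NULL continuation — an architecture has
at least one domain, so $p(\varnothing\,|\,\varnothing) = 0$ and the model
is a proper distribution over non-empty sequences. The start factor under a
zero-count model is therefore $1/N_D$ while all other factors are
$1/(N_D+1)$. Whether boundary contexts should be smoothed differently from
interior ones is genuinely open; we smooth them identically and expose the
choice in one place (`build_model()`). The default pseudocount is
$k = 1/N_D$ (about $0.0009$ at a metazoan-scale alphabet of 1132
superfamilies), which offsets the $O(N_D)$ pseudocounts added per context:
large enough that unobserved combinations can occur in long simulations,
small enough not to swamp the data.

## The chain

Each iteration proposes one move. A gain is proposed with odds roughly
$N_D : 1$ over a loss — mirroring the adjacency counts, so that all
neighbouring states are proposed with comparable probability — then the
site (and token, for gains) is drawn uniformly. The proposal is accepted
with probability $\min(1,\; p_t/p_s)$. Under the first-order factorisation
almost everything cancels; for a gain of token $x$ between $l$ and $r$,

$$ \frac{p_t}{p_s} = \frac{p(x|l)\,p(r|x)}{p(r|l)}, $$

and the deletion ratio is the reciprocal form. The implementation computes
these three-factor ratios in log space and is tested (to $10^{-12}$
relative error) against the full ratio of two architecture probabilities.

Three proposal modes are provided. `"paper"` draws a gain when a uniform
variate exceeds $1/N_D$ (gain odds $N_D - 1 : 1$). `"symmetric"` uses gain
odds $N_D : 1$; the two differ by $O(1/N_D^2)$ per step. A short
calculation shows the symmetric law is *exactly* symmetric: a gain at one
of $n+1$ sites with one of $N_D$ tokens has proposal probability
$\frac{N_D}{N_D+1}\cdot\frac{1}{(n+1)N_D} = \frac{1}{(n+1)(N_D+1)}$, and
the reverse deletion from length $n+1$ has probability
$\frac{1}{N_D+1}\cdot\frac{1}{n+1}$ — identical, for every $n$. The veto of
extinction only adds a self-loop and does not disturb detailed balance.
`"exact-hastings"` therefore folds in a proposal-ratio correction that is
identically one under the symmetric law (the general formula is applied, so
a user-biased proposal still gets corrected), and its stationary
distribution is provably proportional to the first-order architecture
probability. This is verified empirically: on a two-token model the
empirical distribution over the fourteen architectures of length at most
three matches the renormalised model probabilities to total-variation
distance well below 0.02 after $10^6$ iterations. The default remains
`"paper"` for fidelity to the published procedure.

Two details follow the published pseudocode. A proposed deletion of a
single-domain architecture is vetoed *after* being drawn, consumes an
iteration of the budget $T$, and is tallied separately from
Metropolis rejections (`veto_consumes_iteration = FALSE` redraws instead).
And $T$ counts *proposed* transitions, not accepted ones; acceptance rates
for gains are low (most random insertions are implausible under the trained
model) while proposed deletions are accepted readily, the imbalance in
proposal odds offsetting the imbalance in acceptance so that accepted gains
and losses balance at equilibrium.

## Tunable parameters

* `k` — add-k pseudocount (dimensionless; default $1/N_D$). Zero disables
  smoothing and disconnects the state space; `run_chain()` then refuses to
  run unless `allow_reducible = TRUE`.
* `T` — chain length in proposed transitions. Mixing is slow relative to
  $T$ because acceptance is rare; on the bundled medium fixture (150
  tokens, 3000 unique DAs) parallel chains pass the Gelman–Rubin
  criterion at $T = 10^6$, which is the length used throughout the
  package's own checks.
* `replicates` — independent chains; `"match-corpus"` uses the number of
  unique training DAs, the convention used for corpus-scale comparisons.
  Each replicate gets its own seed derived from the master seed
  (`sample.int` on the seeded master stream), so any replicate can be
  re-run alone.
* `proposal_mode`, `gain_loss_bias` — see above; a bias other than 1
  breaks the uniform-proposal property and with it the convergence
  guarantee, and is exposed for experimentation only.
* `trace_every` — cadence of the length trace (default 100, the cadence
  used for the convergence diagnostics).

## Diagnostics and evaluation

`gelman_rubin()` computes the classic potential scale reduction factor on
the second half of each chain's length trace ($\hat R < 1.1$ as the
conventional convergence verdict; a Brooks–Gelman-corrected variant is
optional). The burn-in fraction (default one half) is a standard choice,
not an estimate.

`comparison_report()` computes, identically on a genuine and a simulated
architecture set: singleton/bigram/trigram frequencies (n-grams include the
NULL boundary pairs, exactly as in training, so evaluation and training are
self-consistent); per-pair co-occurrence counts (number of unique DAs
containing both domains anywhere); unique-neighbour counts (distinct
adjacent partners; termini excluded, self-adjacency counts); weighted
bigram promiscuity; per-superfamily tandem-array statistics (a tandem array
is a maximal run of $\ge 2$ identical adjacent tokens); and matched
quantiles of the architecture log-probability distributions after trimming
the longest 1% of each set independently (type-7 quantile interpolation;
length ties trimmed lower-probability-first). Key universes for the paired
correlations are the union of keys observed in either set, zero-filled
(an intersection-only mode exists). Two conventions are fixed here because
the underlying literature leaves them open: monogram frequencies count
occurrences with multiplicity within each unique DA (a presence mode is
available), and event-position histograms bin accepted events by the
*pre-move* architecture length.

The weighted bigram promiscuity formula deserves a note: the cited measure
is not given in closed form in the sources we follow, so the package
implements a documented, swappable stand-in —
$\mathrm{score}(d) = \sum_{p \in \mathrm{partners}(d)}
1/|\mathrm{partners}(p)|$ on unique DAs — which rewards domains whose
partners are themselves choosy. It lives in one function
(`weighted_bigram_promiscuity()`) so an alternative definition can be
substituted without touching callers.

## The synthetic generator

Because corpus-scale validation needs a known truth, `sample_ground_truth()`
draws a complete first-order model and `sample_corpus()` samples unique
architectures from it ancestrally (first token from the NULL context,
successive tokens until NULL; empty draws are impossible by construction;
duplicates are re-drawn up to a retry cap). The generator emulates the
summary shape of genuine metazoan training corpora:

* **Sparse, concentrated transitions.** Genuine corpora of ~1100
  superfamilies contain only ~2900 distinct bigrams. `transition_sparsity`
  zeroes most token-to-token cells and `weight_concentration` (Gamma shape
  < 1) makes the surviving conditionals Zipf-like.
* **Scale-free promiscuity.** Whether a transition $(i,j)$ is allowed
  depends on heavy-tailed per-token weights, giving a few hub domains with
  dozens of partners and many near-dedicated domains, as in genuine domain
  co-occurrence networks.
* **Tandem-prone superfamilies.** A fraction (`tandem_propensity`) of the
  most promiscuous tokens get boosted self-transitions and halved
  termination, emulating repeat-forming superfamilies (immunoglobulins,
  ARM repeats, zinc fingers) whose arrays dominate tandem statistics.
* **Finite, right-skewed lengths.** Per-context termination probabilities
  are drawn around `termination_strength` and bounded away from zero, so
  the closed-form expected length $r_0'(I-Q)^{-1}\mathbf 1$
  (`expected_architecture_length()`) is finite; deduplication of common
  short architectures then skews the unique-corpus length distribution
  right, as in genuine data.

`make_paperlike_fixture()` freezes two presets: `small` (20 tokens, 200
unique DAs; seconds-scale tests) and `medium` (150 tokens, 3000 unique DAs;
mean unique-DA length ≈ 5.5, median 5, tuned into the 3–6 band of genuine
metazoan corpora). Both are fixed-seed and byte-identical across runs. The
presets are deliberately far below genuine scale (~1100 tokens, ~7000 DAs)
so the full battery runs routinely; the problem sizes used by the package's
own checks are the fixture sizes and $T = 10^6$ with 3000 replicates.

What the generator does *not* emulate: genuine data contain higher-order
(beyond-bigram) structure, selection, and extreme outliers (titin-scale
architectures of hundreds of domains). Passing the recapitulation tests on
synthetic corpora therefore shows the machinery is self-consistent — the
simulator reproduces the order/adjacency statistics of a corpus whose
truth is first-order — not that genuine evolution is first-order. On
genuine data the published experience is that co-occurrence-class
statistics agree less well than n-gram frequencies, precisely because they
carry longer-range structure.

One consequence of deduplication is worth stating: parameter recovery
(training estimates converging to the generator's conditionals) is assessed
on *undeduplicated* draws. The estimator is consistent for independent
draws, whereas capping every architecture at one copy distorts frequencies
more, not less, as the corpus grows — deduplication is a treatment for
gene-duplication redundancy in genuine data, not part of the iid sampling
model.

## Numerical choices and edge cases

* All probability calculus is in log space; the three-factor ratio forms
  are used in the inner loop and cross-checked against full differences of
  log-probabilities.
* With $k = 0$, unseen bigrams give ratio exactly 0 (never accepted) or
  $+\infty$ (always accepted) rather than NaN.
* Ties: deduplication orders architectures lexicographically; equal region
  starts in annotation files are broken by region end, then superfamily
  id; promiscuity ranking ties are lexicographic; quantile trimming drops
  lower-probability architectures first among equal lengths.
* The chain inner loop is compiled (Rcpp) and consumes R's RNG in a fixed
  per-iteration draw order; a pure-R reference engine (`engine = "r"`)
  replays the identical stream and is tested for bit-identity with the
  compiled loop.
* Identical chains give a between-chain variance of exactly zero and a
  shrink factor of $\sqrt{(n-1)/n} \lesssim 1$; the diagnostic errors out
  if the within-chain variance is zero.

## A worked example

```{r example, eval = FALSE}
fx <- make_paperlike_fixture("small")       # known first-order truth
model <- build_model(count_ngrams(fx$corpus), k = "default")

reps <- run_replicates(model, simulation_config(
  T = 2e5, replicates = 200, seed = 1), keep_traces = FALSE)

comparison_report(fx$corpus, reps$finals, model)
```

## Limitations

The simulator models single-domain gains and losses only: no explicit
duplication events (tandem repeats emerge from bigram statistics alone,
which underproduces the most extreme genuine arrays), no multi-domain
events, no replacement, no waiting times (iterations are proposal counts,
not time), and no evolution along gene trees. The first-order approximation
cannot, by construction, encode constraints between non-adjacent domains;
that it nevertheless recovers co-occurrence and promiscuity patterns is the
interesting empirical finding the evaluation battery probes.
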