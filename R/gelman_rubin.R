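# Gelman-Rubin potential scale reduction factor (the "shrink" factor) on
# periodically sampled architecture lengths from parallel chains.

#' Gelman-Rubin convergence diagnostic
#'
#' Computes the potential scale reduction factor (PSRF) over two or more
#' parallel chains of equal length, after discarding an initial burn-in
#' fraction of every chain. With m chains of n retained samples, within-chain
#' variance `W` = mean of the per-chain sample variances and between-chain
#' variance `B` = n * variance of the chain means, the pooled posterior
#' variance estimate is `V = (n - 1)/n * W + B/n` and
#' `PSRF = sqrt(V / W)`. The `"corrected"` variant adds the
#' sampling-variability term, `PSRF = sqrt((m + 1)/m * V/W - (n - 1)/(m n))`.
#' Values below about 1.1 are conventionally taken as evidence of approximate
#' convergence; identical chains give B = 0 and a PSRF slightly below 1.
#'
#' @param chains A numeric matrix (rows = samples, columns = chains), or a
#'   list of equal-length numeric vectors, e.g. the `sampled_lengths$length`
#'   series of several [run_chain()] traces.
#' @param discard_first Fraction of each chain discarded as burn-in before
#'   the variances are computed (default 0.5, i.e. the diagnostic uses the
#'   second half of every chain).
#' @param variant `"classic"` (default) or `"corrected"` (see above).
#' @param threshold Convergence threshold for the verdict (default 1.1).
#' @return List: `psrf`, `converged` (`psrf < threshold`), `W`, `B`,
#'   `n_samples` (retained per chain), `n_chains`.
#' @export
gelman_rubin <- function(chains, discard_first = 0.5,
                         variant = c("classic", "corrected"),
                         threshold = 1.1) {
  variant <- match.arg(variant)
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stop("chains must all have the same length")
    chains <- do.call(cbind, chains)
  }
  if (!is.matrix(chains) || ncol(chains) < 2L)
    stop("need at least 2 chains")
  n_total <- nrow(chains)
  from <- floor(discard_first * n_total) + 1L
  x <- chains[from:n_total, , drop = FALSE]
  n <- nrow(x); m <- ncol(x)
  if (n < 10L) stop("need at least 10 retained samples per chain")

  means <- colMeans(x)
  W <- mean(apply(x, 2L, var))
  B <- n * var(means)
  if (W == 0)
    stop("zero within-chain variance; the diagnostic is undefined")
  V <- (n - 1) / n * W + B / n
  psrf <- if (variant == "classic") sqrt(V / W)
          else sqrt((m + 1) / m * V / W - (n - 1) / (m * n))
  list(psrf = psrf, converged = psrf < threshold, W = W, B = B,
       n_samples = n, n_chains = m)
}
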