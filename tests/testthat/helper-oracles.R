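# Independent brute-force oracles, deliberately written as naive scans so
# they share no code with the implementation.

cooccurrence_oracle <- function(corpus) {
  toks <- sort(unique(unlist(corpus)))
  out <- numeric(0)
  for (i in seq_along(toks)) for (j in seq_along(toks)) {
    if (i >= j) next
    cnt <- 0
    for (da in corpus)
      if (toks[i] %in% da && toks[j] %in% da) cnt <- cnt + 1
    if (cnt > 0) out[paste(toks[i], toks[j])] <- cnt
  }
  out
}

neighbor_oracle <- function(corpus) {
  toks <- sort(unique(unlist(corpus)))
  res <- stats::setNames(integer(length(toks)), toks)
  for (tk in toks) {
    partners <- character(0)
    for (da in corpus) {
      for (i in seq_along(da)) {
        if (da[i] != tk) next
        if (i > 1) partners <- union(partners, da[i - 1])
        if (i < length(da)) partners <- union(partners, da[i + 1])
      }
    }
    res[tk] <- length(partners)
  }
  res
}

tandem_oracle <- function(corpus) {
  rows <- list()
  for (da in corpus) {
    i <- 1
    while (i <= length(da)) {
      j <- i
      while (j < length(da) && da[j + 1] == da[i]) j <- j + 1
      if (j > i)
        rows[[length(rows) + 1]] <- data.frame(tok = da[i], len = j - i + 1)
      i <- j + 1
    }
  }
  if (!length(rows))
    return(data.frame(superfamily = character(), total = integer(),
                      max = integer(), n_arrays = integer(), mean = numeric(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  sp <- split(df$len, df$tok)
  out <- data.frame(
    superfamily = names(sp),
    total = vapply(sp, function(v) sum(v), numeric(1)),
    max = vapply(sp, function(v) max(v), numeric(1)),
    n_arrays = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$total <- as.integer(out$total); out$max <- as.integer(out$max)
  out <- out[order(-out$total, out$superfamily, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Classic PSRF computed directly from its definition (no burn-in handling;
# pass the retained samples).
psrf_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  W <- sum(apply(x, 2, function(col) sum((col - mean(col))^2) / (n - 1))) / m
  B <- n / (m - 1) * sum((mu - mean(mu))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}
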