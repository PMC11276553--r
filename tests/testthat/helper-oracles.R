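# Independent oracles used by the tests; deliberately naive so they share no
# code path with the package implementation.

# Exhaustive nearest-neighbor search over explicit pairwise distances.
brute_knn <- function(points, times, query_time, k, mode) {
  i <- which(times == query_time)
  cand <- if (mode == "cccm") which(times < query_time) else setdiff(seq_along(times), i)
  d <- apply(points[cand, , drop = FALSE], 1L,
             function(row) sqrt(sum((row - points[i, ])^2)))
  o <- order(d, times[cand])[seq_len(k)]
  list(times = times[cand][o], distances = unname(d[o]))
}

# Direct convolution with zero pre-history for the FIR generators.
brute_fir <- function(x, taps) {
  lags <- as.integer(names(taps))
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_along(lags)) {
      src <- t - lags[j]
      if (src >= 1L) y[t] <- y[t] + taps[[j]] * x[src]
    }
  }
  y
}

# One row of per-seed statistics per seed.
seed_stats <- function(seeds, fn) {
  do.call(rbind, lapply(seeds, function(s) rbind(fn(s))))
}
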