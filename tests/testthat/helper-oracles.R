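# Independent brute-force oracle for spike detection: every strict local
# maximum above `level`, pruned greedily by amplitude (ties to the earlier
# sample) with a refractory separation. Deliberately loop-based and
# separate from the package's vectorized implementation.
oracle_detect <- function(v, fs, level = -10, refractory_ms = 3) {
  cand <- integer(0)
  for (i in 2:(length(v) - 1L)) {
    if (v[i] > v[i - 1L] && v[i] > v[i + 1L] && v[i] > level) {
      cand <- c(cand, i)
    }
  }
  min_sep <- refractory_ms / 1000 * fs
  kept <- integer(0)
  for (i in cand[order(-v[cand], cand)]) {
    ok <- TRUE
    for (k in kept) if (abs(i - k) < min_sep) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# Hand-rolled step-up BH oracle (independent of stats::p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (r in m:1) {
    prev <- min(prev, m * p[o[r]] / r)
    adj[o[r]] <- min(prev, 1)
  }
  adj
}

# Build a triangular "spike" bump on a trace (for hand-constructed cases).
add_bump <- function(v, at, half_width, height, base) {
  idx <- (at - half_width):(at + half_width)
  shape <- height * (1 - abs(idx - at) / half_width)
  v[idx] <- base + shape
  v
}
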