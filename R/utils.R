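# Internal numeric helpers shared across modules.

# Centered moving mean; ends shrink to the available samples.
moving_mean <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  half <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Strict local maxima indices (greater than both neighbours).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# Greedy refractory pruning: keep candidates in decreasing order of height
# (ties to the earlier sample), dropping any within min_sep of an accepted
# one. Returns accepted indices in time order.
prune_refractory <- function(idx, height, min_sep) {
  if (length(idx) == 0L) return(integer(0))
  ord <- order(-height, idx)
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - keep) >= min_sep)) keep <- c(keep, idx[i])
  }
  sort(keep)
}

# Topographic prominence of peaks at indices `peaks` in `x`: height above
# the higher of the two key saddles (lowest point between the peak and the
# nearest higher terrain on each side; trace end counts as a boundary).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1L) x[seq_len(p - 1L)] else numeric(0)
    right <- if (p < length(x)) x[(p + 1L):length(x)] else numeric(0)
    hi_l <- which(left >= h)
    base_l <- if (length(hi_l)) min(left[(max(hi_l)):(p - 1L)]) else
      if (length(left)) min(left) else h
    hi_r <- which(right >= h)
    base_r <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else
      if (length(right)) min(right) else h
    h - max(base_l, base_r)
  }, numeric(1))
}

# First index i (at or after `from`) with x crossing `level` going up
# (x[i-1] < level <= x[i]); returns the interpolated fractional index.
cross_up <- function(x, level, from = 2L) {
  for (i in seq(max(from, 2L), length(x))) {
    if (x[i - 1L] < level && x[i] >= level) {
      return(i - 1L + (level - x[i - 1L]) / (x[i] - x[i - 1L]))
    }
  }
  NA_real_
}

# First downward crossing (x[i-1] >= level > x[i]) at or after `from`.
cross_down <- function(x, level, from = 2L) {
  for (i in seq(max(from, 2L), length(x))) {
    if (x[i - 1L] >= level && x[i] < level) {
      return(i - 1L + (x[i - 1L] - level) / (x[i - 1L] - x[i]))
    }
  }
  NA_real_
}

# Linear interpolation of x at fractional index fi (1-based).
value_at <- function(x, fi) {
  lo <- floor(fi); hi <- ceiling(fi)
  if (lo < 1 || hi > length(x)) return(NA_real_)
  if (lo == hi) return(x[lo])
  x[lo] + (fi - lo) * (x[hi] - x[lo])
}

# Localized RNG: run expr with a private seed, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(expr)
}

# Derive a stream of child seeds below 2^31 from one master seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
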