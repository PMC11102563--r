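#' Detect action-potential apexes in a current-clamp trace
#'
#' Apexes are strict local maxima exceeding `cfg$spike$detect_level`
#' (default -10 mV) separated by at least the refractory interval (default
#' 3 ms). When two candidates fall within the refractory interval the
#' larger-amplitude one wins, ties going to the earlier sample.
#'
#' @param trace numeric vector of membrane potential, mV.
#' @param sampling_rate Hz.
#' @param cfg an [analysis_config()].
#' @return Integer vector of apex sample indices, ordered in time (possibly
#'   empty).
#' @export
detect_spikes <- function(trace, sampling_rate, cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"), sampling_rate > 0)
  cand <- local_maxima(trace)
  cand <- cand[trace[cand] > cfg$spike$detect_level]
  min_sep <- cfg$spike$refractory_ms / 1000 * sampling_rate
  prune_refractory(cand, trace[cand], min_sep)
}

#' Total evoked action potentials over the counted steps
#'
#' Sums spike counts over the first `cfg$n_steps_counted` depolarization
#' steps (32 for dopaminergic, 30 for hippocampal neurons). Cells whose
#' holding current exceeds `cfg$holding_current_max` (50 pA) in magnitude
#' are excluded rather than scored.
#'
#' @param sweeps a current-clamp [sweep_set()].
#' @param cfg an [analysis_config()].
#' @return List with `total` (integer or `NA` when excluded), `per_step`
#'   counts, `excluded` flag and `reason`.
#' @export
count_evoked_aps <- function(sweeps, cfg = analysis_config()) {
  stopifnot(inherits(sweeps, "sweep_set"),
            sweeps$protocol$mode == "current_clamp")
  if (nrow(sweeps$traces) < cfg$n_steps_counted) {
    stop("count_evoked_aps: ", nrow(sweeps$traces), " sweeps but ",
         cfg$n_steps_counted, " counted steps requested")
  }
  if (abs(sweeps$holding_current) > cfg$holding_current_max) {
    return(list(total = NA_integer_, per_step = NULL, excluded = TRUE,
                reason = sprintf("holding>%gpA", cfg$holding_current_max)))
  }
  per_step <- vapply(seq_len(cfg$n_steps_counted), function(s) {
    length(detect_spikes(sweeps$traces[s, ], sweeps$sampling_rate, cfg))
  }, integer(1))
  list(total = sum(per_step), per_step = per_step, excluded = FALSE,
       reason = NA_character_)
}

# First strict local maximum (plateau-aware: the centre of a maximal run of
# near-equal values that stands above its neighbours) of x over indices
# [from, to]. Returns NA if none.
first_local_max_run <- function(x, from, to) {
  from <- max(from, 2L); to <- min(to, length(x) - 1L)
  if (from > to) return(NA_integer_)
  tol <- 1e-9 * max(abs(x[is.finite(x)]), 1e-300)
  i <- from
  while (i <= to) {
    j <- i
    while (j < length(x) && abs(x[j + 1L] - x[i]) <= tol) j <- j + 1L
    if (i > 1L && j < length(x) &&
        x[i - 1L] < x[i] - tol && x[j + 1L] < x[i] - tol) {
      return(as.integer(round((i + j) / 2)))
    }
    i <- j + 1L
  }
  NA_integer_
}

#' Rheobase-spike shape features
#'
#' Analyzes the first spike generated with the least injected current: the
#' first apex of the lowest step that evokes any spike. The threshold is the
#' membrane potential at the first maximum of the second derivative of
#' voltage versus time on the rising phase (second differences of a lightly
#' smoothed trace, searched over the `d2_window_ms` preceding the apex);
#' amplitude is apex minus threshold; width is the time between the rising
#' and falling crossings of threshold plus half the amplitude (full width at
#' half maximum, sub-sample interpolated); the fast afterhyperpolarization
#' is threshold minus the potential `fahp_delay` (5) ms after the potential
#' returns to the threshold on the falling phase.
#'
#' @param sweeps a current-clamp [sweep_set()].
#' @param cfg an [analysis_config()].
#' @return List of class `spike_features`: `rheobase_step` (1-based sweep
#'   index), `threshold_mV`, `amplitude_mV`, `width_ms`, `fahp5_mV`,
#'   `apex_index`.
#' @export
spike_shape <- function(sweeps, cfg = analysis_config()) {
  stopifnot(inherits(sweeps, "sweep_set"),
            sweeps$protocol$mode == "current_clamp")
  fs <- sweeps$sampling_rate
  rheo <- NA_integer_; apex <- NA_integer_
  for (s in seq_len(nrow(sweeps$traces))) {
    ap <- detect_spikes(sweeps$traces[s, ], fs, cfg)
    if (length(ap) > 0) { rheo <- s; apex <- ap[1L]; break }
  }
  if (is.na(rheo)) stop("spike_shape: no rheobase spike in any sweep")
  v <- sweeps$traces[rheo, ]

  sm <- moving_mean(v, cfg$spike$d2_smooth)
  d2 <- c(0, diff(diff(sm)), 0)  # central second difference at i
  win <- as.integer(round(cfg$spike$d2_window_ms / 1000 * fs))
  w0 <- max(apex - win, 2L); w1 <- apex - 1L
  # anchor the search to the steep rising phase: start just before the
  # last point whose slope is below 10% of the maximal rise, so curvature
  # fluctuations in the subthreshold approach cannot pre-empt the onset
  d1 <- c(0, diff(sm))
  slopes <- d1[w0:apex]
  steepest <- which.max(slopes)
  shallow <- which(slopes[seq_len(steepest)] < 0.1 * slopes[steepest])
  if (length(shallow)) {
    t_steep <- w0 + max(shallow) - 1L
    w0 <- max(w0, t_steep - as.integer(round(0.0005 * fs)))
  }
  d2w <- d2[w0:w1]
  # suppress curvature indistinguishable from rounding noise so that flat
  # segments do not produce spurious "first" maxima
  top <- max(d2w, 0)
  if (top > 0) d2w[d2w < 0.05 * top] <- 0
  i_loc <- first_local_max_run(d2w, 2L, length(d2w) - 1L)
  if (is.na(i_loc)) i_loc <- which.max(d2w)
  i_thr <- w0 + i_loc - 1L
  threshold <- v[i_thr]
  amplitude <- v[apex] - threshold

  half <- threshold + amplitude / 2
  i_up <- cross_up(v, half, from = i_thr)
  i_dn <- cross_down(v, half, from = apex + 1L)
  width_ms <- if (is.na(i_up) || is.na(i_dn)) NA_real_
              else (i_dn - i_up) / fs * 1000

  # falling-phase return to threshold (reaching it exactly counts)
  i_ret <- NA_real_
  for (i in (apex + 1L):length(v)) {
    if (v[i] <= threshold) {
      i_ret <- if (v[i] == threshold || i == 1L) as.numeric(i)
               else (i - 1L) + (v[i - 1L] - threshold) / (v[i - 1L] - v[i])
      break
    }
  }
  fahp5 <- if (is.na(i_ret)) NA_real_ else {
    fi <- i_ret + cfg$fahp_delay / 1000 * fs
    if (fi > length(v)) NA_real_ else threshold - value_at(v, fi)
  }

  structure(list(rheobase_step = rheo, apex_index = apex,
                 threshold_mV = threshold, amplitude_mV = amplitude,
                 width_ms = width_ms, fahp5_mV = fahp5),
            class = "spike_features")
}

#' @export
print.spike_features <- function(x, ...) {
  cat(sprintf(paste0("<spike_features> step %d: threshold %.2f mV, ",
                     "amplitude %.2f mV, width %.3f ms, fAHP(5ms) %.2f mV\n"),
              x$rheobase_step, x$threshold_mV, x$amplitude_mV, x$width_ms,
              x$fahp5_mV))
  invisible(x)
}
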