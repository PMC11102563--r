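#' Detect spontaneous EPSCs in a gap-free voltage-clamp trace
#'
#' Events are negative deflections below a rolling-median baseline
#' exceeding `threshold_sd` times the robust noise scale (1.4826 x MAD of
#' the baseline-subtracted trace), separated by at least `min_interval_ms`
#' (the deeper trough wins within an interval). Candidate troughs are
#' located on a copy smoothed with a `smooth_ms` moving mean, so that
#' single-sample noise excursions cannot trigger the detector; synaptic
#' events (millisecond rise times) pass the filter nearly unattenuated.
#' One event is scored per below-threshold excursion, and the detector
#' re-arms only after the trace recovers above half the threshold, so a
#' slow decay tail cannot re-trigger it. The baseline median spans
#' `baseline_window_s` (computed on a 10x decimated copy and interpolated
#' back, which leaves millisecond-scale events untouched). Event amplitude
#' is the absolute difference between baseline and trough. Cells with no
#' events are retained with rate 0.
#'
#' @param trace an [np_trace()] (pA) or numeric vector.
#' @param cfg an [analysis_config()].
#' @param sampling_rate Hz; required when `trace` is a bare vector.
#' @return List of class `synaptic_summary`: `n_events`, `rate_hz`
#'   (events / recording duration, 0 for silent cells), `mean_amplitude_pA`
#'   (`NA` when no events), `amplitudes`, `event_times_s`.
#' @export
detect_epscs <- function(trace, cfg = analysis_config(),
                         sampling_rate = NULL) {
  if (inherits(trace, "np_trace")) {
    x <- trace$samples; fs <- trace$sampling_rate
  } else {
    stopifnot(!is.null(sampling_rate))
    x <- as.numeric(trace); fs <- sampling_rate
  }
  n <- length(x)
  duration <- n / fs

  dec <- 10L
  xd <- x[seq(1L, n, by = dec)]
  k <- as.integer(round(cfg$epsc$baseline_window_s * fs / dec))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(xd) %% 2L == 1L) length(xd) else length(xd) - 1L)
  base_d <- if (k >= 3L) stats::runmed(xd, k) else xd
  baseline <- stats::approx(seq(1L, n, by = dec), base_d, xout = seq_len(n),
                            rule = 2)$y
  d <- x - baseline

  # detect on a lightly smoothed copy (sub-millisecond moving mean) so that
  # single-sample noise excursions cannot cross the threshold, which is
  # still scaled to the raw robust noise estimate
  k_sm <- max(1L, as.integer(round(cfg$epsc$smooth_ms / 1000 * fs)))
  ds <- moving_mean(d, k_sm)
  sigma <- stats::mad(d)
  ev_idx <- integer(0)
  if (sigma > 0) {
    thr <- -cfg$epsc$threshold_sd * sigma
    rearm <- thr / 2
    below <- ds < thr
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    if (nrow(runs) > 0) {
      # merge excursions not separated by a recovery above the re-arm
      # level (half threshold): a decay tail cannot re-trigger
      merged <- list(runs[1, ])
      if (nrow(runs) > 1) {
        for (i in 2:nrow(runs)) {
          prev <- merged[[length(merged)]]
          gap <- ds[(prev[2] + 1L):(runs[i, 1] - 1L)]
          if (length(gap) == 0 || max(gap) < rearm) {
            merged[[length(merged)]] <- c(prev[1], runs[i, 2])
          } else {
            merged[[length(merged) + 1L]] <- runs[i, ]
          }
        }
      }
      ev_idx <- vapply(merged, function(rg) {
        rg[1] - 1L + which.min(ds[rg[1]:rg[2]])
      }, integer(1))
      min_sep <- cfg$epsc$min_interval_ms / 1000 * fs
      ev_idx <- prune_refractory(ev_idx, -ds[ev_idx], min_sep)
    }
  }
  amps <- -ds[ev_idx]
  structure(list(n_events = length(ev_idx),
                 rate_hz = length(ev_idx) / duration,
                 mean_amplitude_pA = if (length(amps)) mean(amps) else NA_real_,
                 amplitudes = amps,
                 event_times_s = (ev_idx - 1L) / fs,
                 duration_s = duration),
            class = "synaptic_summary")
}

#' @export
print.synaptic_summary <- function(x, ...) {
  cat(sprintf("<synaptic_summary> %d events in %g s (%.3f Hz), mean %.1f pA\n",
              x$n_events, x$duration_s, x$rate_hz,
              if (is.na(x$mean_amplitude_pA)) NA else x$mean_amplitude_pA))
  invisible(x)
}

#' Pooled empirical cumulative distribution of EPSC amplitudes per group
#'
#' @param amplitudes named list, one numeric vector of pooled amplitudes
#'   (pA) per group; every group must contain at least one amplitude.
#' @return Named list of `ecdf` step functions (right-continuous,
#'   `F(max) = 1`), one per group.
#' @export
pooled_ecdf <- function(amplitudes) {
  stopifnot(is.list(amplitudes), length(amplitudes) >= 1)
  lapply(stats::setNames(names(amplitudes), names(amplitudes)), function(g) {
    a <- amplitudes[[g]]
    if (length(a) == 0) stop("pooled_ecdf: empty group '", g, "'")
    stats::ecdf(a)
  })
}

#' Tabulate an ECDF on its jump points (for TSV export)
#'
#' @param f an `ecdf` function.
#' @return data.frame with `amplitude` and `F`.
#' @export
ecdf_table <- function(f) {
  x <- stats::knots(f)
  data.frame(amplitude = x, F = f(x))
}
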