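#' Classify calcium-imaging ROIs into neurons, astrocytes and inactive cells
#'
#' Per ROI, the lag-`lag_frames` (default 6 frames, ~0.6 s at 10 Hz)
#' fluorescence differences are normalized by the trace's peak-to-trough
#' amplitude over the entire recording; an ROI whose maximum normalized
#' difference exceeds `neuron_threshold` (0.05) is an active neuron (fast
#' transients rise steeply). For the remaining ROIs a fluorescence ratio
#' delta-f/f0 is computed as (max - min) / baseline, the baseline being the
#' lowest value of the signal; ROIs whose ratio falls below
#' `inactive_fraction` (10%) of the largest ratio among the non-neuron ROIs
#' (the most active astrocyte) are inactive, the rest active astrocytes.
#' Constant traces are inactive by convention (never a division error).
#'
#' @param fluor a [fluor_matrix()].
#' @param cfg an [analysis_config()].
#' @return data.frame of class `roi_classification`: `roi_id`, `label`,
#'   `max_norm_delta`, `fluor_ratio` (ratio is `NA` for neurons).
#' @export
classify_rois <- function(fluor, cfg = analysis_config()) {
  stopifnot(inherits(fluor, "fluor_matrix"))
  lag <- cfg$calcium$lag_frames
  F <- fluor$F
  if (ncol(F) <= lag) stop("classify_rois: need more frames than lag_frames")

  n <- nrow(F)
  max_norm_delta <- numeric(n)
  ratio <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    f <- F[r, ]
    rng <- max(f) - min(f)
    max_norm_delta[r] <- if (rng == 0) 0 else {
      dl <- f[(lag + 1L):length(f)] - f[seq_len(length(f) - lag)]
      max(dl) / rng
    }
  }
  is_neuron <- max_norm_delta > cfg$calcium$neuron_threshold
  for (r in which(!is_neuron)) {
    f <- F[r, ]
    baseline <- min(f)
    if (baseline <= 0) {
      stop("classify_rois: ROI ", rownames(F)[r], " has baseline <= 0; ",
           "apply an offset correction before classification")
    }
    ratio[r] <- (max(f) - baseline) / baseline
  }
  label <- rep("active_neuron", n)
  if (any(!is_neuron)) {
    ref <- max(ratio[!is_neuron])
    inactive <- !is_neuron &
      (ratio == 0 | ratio < cfg$calcium$inactive_fraction * ref)
    label[!is_neuron] <- ifelse(inactive[!is_neuron], "inactive",
                                "active_astrocyte")
  }
  out <- data.frame(roi_id = fluor$roi_ids, label = label,
                    max_norm_delta = max_norm_delta, fluor_ratio = ratio,
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_classification", class(out))
  out
}

#' Count fast calcium transient events of an active neuron
#'
#' Peaks are local maxima with topographic prominence of at least
#' `prominence_fraction` (0.2) of the trace's peak-to-trough amplitude,
#' separated by at least `min_event_sep_frames` (5) frames.
#'
#' @param trace numeric fluorescence vector of one active-neuron ROI.
#' @param frame_rate Hz.
#' @param cfg an [analysis_config()].
#' @return List with `n_events`, `rate_hz`, `peak_frames`.
#' @export
count_neuron_events <- function(trace, frame_rate,
                                cfg = analysis_config()) {
  rng <- max(trace) - min(trace)
  peaks <- local_maxima(trace)
  if (length(peaks) > 0 && rng > 0) {
    prom <- peak_prominence(trace, peaks)
    peaks <- peaks[prom >= cfg$calcium$prominence_fraction * rng]
    peaks <- prune_refractory(peaks, trace[peaks],
                              cfg$calcium$min_event_sep_frames)
  } else {
    peaks <- integer(0)
  }
  list(n_events = length(peaks),
       rate_hz = length(peaks) / (length(trace) / frame_rate),
       peak_frames = peaks)
}

#' Mean fluorescence ratio of the most active astrocytes
#'
#' Averages the delta-f/f0 fluorescence ratio of the `n_top_astrocytes`
#' (default 3) astrocytes with the highest ratios; with fewer astrocytes
#' than that, all are averaged and the result is flagged.
#'
#' @param classification a [classify_rois()] result.
#' @param cfg an [analysis_config()].
#' @return List with `mean_ratio` (`NA` with a warning when the recording
#'   has no astrocytes), `n_used`, `flagged_short` (fewer astrocytes than
#'   requested).
#' @export
astrocyte_summary <- function(classification, cfg = analysis_config()) {
  astro <- classification$fluor_ratio[
    classification$label == "active_astrocyte"]
  k <- cfg$calcium$n_top_astrocytes
  if (length(astro) == 0) {
    warning("astrocyte_summary: no astrocytes in recording")
    return(list(mean_ratio = NA_real_, n_used = 0L, flagged_short = TRUE))
  }
  top <- sort(astro, decreasing = TRUE)[seq_len(min(k, length(astro)))]
  list(mean_ratio = mean(top), n_used = length(top),
       flagged_short = length(astro) < k)
}

# Rolling-window Pearson correlations between rows i and j of a matrix,
# window w, stride 1, via cumulative sums. Zero-variance windows -> 0.
rolling_cor <- function(x, y, w) {
  n <- length(x)
  roll <- function(v) {
    cs <- cumsum(c(0, v))
    cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
  }
  sx <- roll(x); sy <- roll(y)
  sxx <- roll(x * x); syy <- roll(y * y); sxy <- roll(x * y)
  vx <- w * sxx - sx^2
  vy <- w * syy - sy^2
  num <- w * sxy - sx * sy
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Windowed pairwise-correlation synchrony of an active-neuron population
#'
#' Traces are smoothed with a moving-average filter (`ma_frames`, default
#' 5), then Pearson correlations are computed for every ROI pair in sliding
#' windows of `corr_window_frames` (35 frames, ~3.5 s at 10 Hz; stride one
#' frame). Each ROI's score is the sum of its windowed correlations with
#' all partners, a measure of how correlated the neuron is with its
#' surround; ROIs are ranked by this sum and the mean over the top `top_k`
#' (10) is the recording's synchrony. Both the raw sum and the normalized
#' score (sum / (partners x windows), in [-1, 1]) are reported.
#' Zero-variance windows contribute 0 by convention.
#'
#' @param fluor a [fluor_matrix()] restricted to active neurons (use
#'   [classify_rois()] to subset), or a plain matrix plus `frame_rate`.
#' @param cfg an [analysis_config()].
#' @return List of class `synchrony_report`: `scores` data.frame (roi_id,
#'   corr_sum, corr_norm, rank), `top_k_mean_raw`, `top_k_mean_norm`,
#'   `n_windows`.
#' @export
synchrony <- function(fluor, cfg = analysis_config()) {
  F <- if (inherits(fluor, "fluor_matrix")) fluor$F else as.matrix(fluor)
  ids <- if (inherits(fluor, "fluor_matrix")) fluor$roi_ids
         else seq_len(nrow(F))
  n <- nrow(F)
  w <- cfg$calcium$corr_window_frames
  if (n < 2) stop("synchrony: need >= 2 neuron ROIs")
  if (ncol(F) < w) stop("synchrony: need at least corr_window_frames frames")

  Fs <- t(apply(F, 1, moving_mean, k = cfg$calcium$ma_frames))
  n_win <- ncol(F) - w + 1L
  sums <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sum(rolling_cor(Fs[i, ], Fs[j, ], w))
      sums[i] <- sums[i] + s
      sums[j] <- sums[j] + s
    }
  }
  norm <- sums / ((n - 1L) * n_win)
  ord <- order(-sums)
  k <- min(cfg$calcium$top_k, n)
  scores <- data.frame(roi_id = ids, corr_sum = sums, corr_norm = norm,
                       rank = match(seq_len(n), ord))
  structure(list(scores = scores,
                 top_k_mean_raw = mean(sums[ord[seq_len(k)]]),
                 top_k_mean_norm = mean(norm[ord[seq_len(k)]]),
                 n_windows = n_win, top_k = k),
            class = "synchrony_report")
}

#' Averaged-periodogram (Welch) power spectral density
#'
#' Splits the signal into `nfft`-sample segments with 50% overlap, removes
#' a linear trend from each, applies a Hann taper, and averages the
#' segment periodograms.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param nfft segment length (default 256); shortened to the signal length
#'   when the signal is shorter.
#' @return List with `freq` (Hz, 0 .. fs/2) and `psd`.
#' @export
welch_psd <- function(x, fs, nfft = 256L) {
  n <- length(x)
  nfft <- min(as.integer(nfft), n)
  step <- max(nfft %/% 2L, 1L)
  starts <- seq(1L, n - nfft + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))  # Hann
  u <- sum(win^2)
  t0 <- seq_len(nfft)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    fit <- stats::lm.fit(cbind(1, t0), seg)
    seg <- fit$residuals * win
    sp <- abs(stats::fft(seg))^2 / (fs * u)
    half <- sp[seq_len(nfft %/% 2L + 1L)]
    half[2:(length(half) - 1L)] <- 2 * half[2:(length(half) - 1L)]
    acc <- acc + half
  }
  list(freq = (seq_len(nfft %/% 2L + 1L) - 1L) * fs / nfft,
       psd = acc / length(starts))
}

#' PSD band-area ratio of the most active neurons
#'
#' Neurons are sorted by their fast-transient event count (descending); for
#' each, the power spectral density is estimated ([welch_psd()]) and the
#' ratio of the area under the PSD over the full spectrum to the area over
#' the high-frequency band (frequencies greater than
#' `psd_high_cutoff_hz`, default 0.1 Hz) is computed by trapezoidal
#' integration. The mean ratio over the top `top_k` neurons is reported.
#' The ratio is >= 1 by construction (the full spectrum contains the high
#' band); a neuron with no high-band power gets an `Inf` sentinel and is
#' flagged.
#'
#' @param fluor a [fluor_matrix()] restricted to active neurons, or matrix.
#' @param frame_rate Hz (taken from `fluor` when available).
#' @param cfg an [analysis_config()].
#' @return List of class `psd_ratio_report`: `ratios` data.frame (roi_id,
#'   event_count, psd_ratio), `top_k_mean`, `flagged_infinite`.
#' @export
psd_ratio <- function(fluor, frame_rate = NULL, cfg = analysis_config()) {
  F <- if (inherits(fluor, "fluor_matrix")) fluor$F else as.matrix(fluor)
  fr <- if (inherits(fluor, "fluor_matrix")) fluor$frame_rate else frame_rate
  ids <- if (inherits(fluor, "fluor_matrix")) fluor$roi_ids
         else seq_len(nrow(F))
  stopifnot(!is.null(fr), nrow(F) >= 1)
  cutoff <- cfg$calcium$psd_high_cutoff_hz

  events <- vapply(seq_len(nrow(F)), function(r)
    count_neuron_events(F[r, ], fr, cfg)$n_events, integer(1))
  ratios <- vapply(seq_len(nrow(F)), function(r) {
    p <- welch_psd(F[r, ], fr, cfg$calcium$psd_nfft)
    full <- pracma::trapz(p$freq, p$psd)
    hi_idx <- p$freq > cutoff
    if (sum(hi_idx) < 2) return(Inf)
    high <- pracma::trapz(p$freq[hi_idx], p$psd[hi_idx])
    if (high <= 0) Inf else full / high
  }, numeric(1))

  ord <- order(-events)
  k <- min(cfg$calcium$top_k, nrow(F))
  top <- ratios[ord[seq_len(k)]]
  structure(list(ratios = data.frame(roi_id = ids, event_count = events,
                                     psd_ratio = ratios),
                 top_k_mean = mean(top[is.finite(top)]),
                 flagged_infinite = any(!is.finite(top)), top_k = k),
            class = "psd_ratio_report")
}
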