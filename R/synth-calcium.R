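#' Parameters for the calcium-imaging population generator
#'
#' Emulates an ROI-averaged fluorescence recording (typically 1800 frames at
#' ~10 Hz) containing three cell classes. Active neurons show fast calcium
#' transients (linear rise completing within the classifier's lag, then an
#' exponential decay) driven by Poisson events; a common event stream
#' adopted per event with probability `shared_drive_fraction` provides an
#' analytic synchrony knob. Active astrocytes show large, slow raised-cosine
#' calcium waves whose period is chosen so the lag-6 normalized difference
#' stays below the neuron threshold by construction. All ROIs additionally
#' carry a slow sinusoidal baseline wander - the dominant amplitude of an
#' inactive ROI - plus small white noise (ROI averaging over many pixels
#' keeps frame-to-frame noise small relative to slow drift).
#'
#' @param n_neurons,n_astrocytes,n_inactive class sizes.
#' @param neuron_event_rate Hz.
#' @param transient_rise_frames,transient_decay_frames transient shape
#'   (rise must complete within the classifier lag of 6 frames).
#' @param transient_amplitude event amplitude, a.u.; jittered uniformly by
#'   +/- `amplitude_jitter` (fractional).
#' @param astro_period_s,astro_amplitude_ratio slow-wave period (s) and
#'   peak amplitude as a fraction of baseline (delta-f/f0).
#' @param baseline_f0 baseline fluorescence, a.u.
#' @param shared_drive_fraction probability a neuron adopts a common-stream
#'   event, in `[0, 1]`.
#' @param drift_amplitude,drift_period_s baseline-wander sinusoid, a.u. / s.
#' @param noise_sd white-noise SD, a.u.
#' @param n_frames,frame_rate recording geometry.
#' @param amplitude_jitter fractional event-amplitude jitter.
#' @return An object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_neurons = 15L, n_astrocytes = 5L,
                               n_inactive = 10L, neuron_event_rate = 0.2,
                               transient_rise_frames = 2L,
                               transient_decay_frames = 8L,
                               transient_amplitude = 40,
                               astro_period_s = 60,
                               astro_amplitude_ratio = 1.0,
                               baseline_f0 = 100,
                               shared_drive_fraction = 0.3,
                               drift_amplitude = 4, drift_period_s = 120,
                               noise_sd = 0.04,
                               n_frames = 1800L, frame_rate = 10,
                               amplitude_jitter = 0.2) {
  stopifnot(n_neurons >= 0, n_astrocytes >= 0, n_inactive >= 0,
            neuron_event_rate >= 0, transient_rise_frames >= 1,
            transient_decay_frames >= 1, astro_period_s >= 30,
            shared_drive_fraction >= 0, shared_drive_fraction <= 1,
            baseline_f0 > 0, noise_sd >= 0, frame_rate > 0)
  if (n_frames < 2L * transient_decay_frames) {
    stop("n_frames must be at least twice transient_decay_frames")
  }
  structure(as.list(environment()), class = "calcium_sim_params")
}

#' Simulate an ROI fluorescence population with known labels
#'
#' @param params a [calcium_sim_params()].
#' @param seed integer seed.
#' @return List with `fluor` (a [fluor_matrix()]) and `truth`: per-ROI class
#'   labels (`"active_neuron"`, `"active_astrocyte"`, `"inactive"`), event
#'   frames per neuron, the common-stream event frames, and the parameters.
#' @export
gen_calcium_population <- function(params = calcium_sim_params(),
                                   seed = NULL) {
  stopifnot(inherits(params, "calcium_sim_params"))
  p <- params
  n_roi <- p$n_neurons + p$n_astrocytes + p$n_inactive
  if (n_roi < 1L) stop("at least one ROI required")
  nf <- as.integer(p$n_frames)
  t_s <- (seq_len(nf) - 1L) / p$frame_rate
  dur <- nf / p$frame_rate

  kern <- c(seq(0, 1, length.out = p$transient_rise_frames + 1L)[-1L],
            exp(-seq_len(6L * p$transient_decay_frames) /
                  p$transient_decay_frames))
  labels <- rep(c("active_neuron", "active_astrocyte", "inactive"),
                c(p$n_neurons, p$n_astrocytes, p$n_inactive))
  F <- matrix(p$baseline_f0, n_roi, max(nf, 1L))
  events <- vector("list", n_roi)

  add_events <- function(row, ev_frames, amps) {
    for (k in seq_along(ev_frames)) {
      i0 <- ev_frames[k]
      i1 <- min(i0 + length(kern) - 1L, nf)
      row[i0:i1] <- row[i0:i1] + amps[k] * kern[seq_len(i1 - i0 + 1L)]
    }
    row
  }

  with_seed(seed, {
    n_common <- stats::rpois(1, p$neuron_event_rate * dur)
    common <- sort(sample.int(nf, min(n_common, nf)))
    for (r in seq_len(n_roi)) {
      drift_phase <- stats::runif(1, 0, 2 * pi)
      drift <- p$drift_amplitude *
        sin(2 * pi * t_s / p$drift_period_s + drift_phase)
      row <- rep(p$baseline_f0, nf) + drift
      if (labels[r] == "active_neuron") {
        take <- common[stats::runif(length(common)) < p$shared_drive_fraction]
        n_own <- stats::rpois(1, (1 - p$shared_drive_fraction) *
                                p$neuron_event_rate * dur)
        own <- if (n_own > 0) sort(sample.int(nf, min(n_own, nf)))
               else integer(0)
        ev <- sort(unique(c(take, own)))
        amps <- p$transient_amplitude *
          stats::runif(length(ev), 1 - p$amplitude_jitter,
                       1 + p$amplitude_jitter)
        row <- add_events(row, ev, amps)
        events[[r]] <- ev
      } else if (labels[r] == "active_astrocyte") {
        phase <- stats::runif(1, 0, 2 * pi)
        wave <- 0.5 * (1 - cos(2 * pi * t_s / p$astro_period_s + phase))
        row <- row + p$baseline_f0 * p$astro_amplitude_ratio * wave
        events[[r]] <- integer(0)
      } else {
        events[[r]] <- integer(0)
      }
      if (p$noise_sd > 0) row <- row + stats::rnorm(nf, 0, p$noise_sd)
      F[r, ] <- row
    }
  })

  list(fluor = fluor_matrix(F, frame_rate = p$frame_rate),
       truth = list(labels = labels, events = events,
                    common_events = common, params = p))
}
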