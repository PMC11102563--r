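#' Parameters for the current-clamp spike-train generator
#'
#' The spike waveform is a parametric template (slow depolarizing ramp to
#' threshold, linear rise to the apex, linear fall back through threshold,
#' descent to the fast-afterhyperpolarization trough 5 ms later, then
#' recovery), not a conductance model: every feature the analysis recovers
#' is exact by construction. Knots are snapped to the sample grid so that
#' interpolated measurements reproduce the template to machine precision.
#'
#' @param rheobase_step 0-based index of the first step that evokes a spike
#'   (`0 <= rheobase_step`; a value `>= n_steps` yields an all-silent cell).
#' @param fi_slope frequency-current gain, spikes per step above rheobase;
#'   step `s >= rheobase_step` carries `max(1, round(fi_slope * (s -
#'   rheobase_step + 1)))` spikes.
#' @param threshold_mV,amplitude_mV,width_ms,fahp5_mV spike template:
#'   threshold voltage, apex height above threshold, full width at half
#'   maximum, and depth of the afterhyperpolarization 5 ms after the
#'   descending threshold crossing.
#' @param noise_sd additive white noise, mV.
#' @param holding_current pA held to keep the cell at rest.
#' @param capacitance pF (metadata carried into the sweep set).
#' @param v_rest resting/holding potential, mV.
#' @param depol_gain subthreshold depolarization per injected pA above
#'   holding, mV/pA (capped 5 mV below threshold).
#' @param ramp_ms,recovery_ms pre-spike ramp and post-fAHP recovery spans.
#' @return An object of class `ephys_sim_params`.
#' @export
ephys_sim_params <- function(rheobase_step = 4L, fi_slope = 0.35,
                             threshold_mV = -40, amplitude_mV = 80,
                             width_ms = 2, fahp5_mV = 8,
                             noise_sd = 0.3, holding_current = 10,
                             capacitance = 30, v_rest = -60,
                             depol_gain = 0.15, ramp_ms = 12,
                             recovery_ms = 8) {
  stopifnot(width_ms > 0, amplitude_mV > 0, rheobase_step >= 0,
            noise_sd >= 0, ramp_ms > 0, recovery_ms > 0)
  structure(as.list(environment()), class = "ephys_sim_params")
}

#' Simulate a current-clamp sweep family with known spike content
#'
#' Generates one sweep per protocol step on the default 38-step, 3 pA,
#' 400 ms ladder. Steps below `rheobase_step` are subthreshold; step `s >=
#' rheobase_step` carries `max(1, round(fi_slope * (s - rheobase_step +
#' 1)))` template spikes placed without overlap.
#'
#' @param params an [ephys_sim_params()].
#' @param protocol a current-clamp [stimulus_protocol()].
#' @param sampling_rate Hz.
#' @param seed integer seed (the generator is deterministic given it).
#' @param cell_id,group_id identifiers.
#' @return List with `sweeps` (a [sweep_set()]) and `truth`: per-step spike
#'   counts, apex sample indices, and the grid-snapped template actually
#'   realized.
#' @export
gen_current_clamp <- function(params = ephys_sim_params(),
                              protocol = stimulus_protocol("current_clamp"),
                              sampling_rate = 20000, seed = NULL,
                              cell_id = "sim", group_id = "sim") {
  stopifnot(inherits(params, "ephys_sim_params"),
            protocol$mode == "current_clamp")
  fs <- sampling_rate
  n_samp <- as.integer(round(protocol$step_duration / 1000 * fs))
  ms <- function(t) as.integer(round(t / 1000 * fs))  # ms -> samples
  t_r <- max(ms(params$width_ms), 1L)
  t_f <- t_r
  ramp <- max(ms(params$ramp_ms), 1L)
  fahp_off <- ms(5)
  rec <- max(ms(params$recovery_ms), 1L)
  footprint <- ramp + t_r + t_f + fahp_off + rec

  counts <- integer(protocol$n_steps)
  s0 <- seq_len(protocol$n_steps) - 1L           # 0-based step index
  above <- s0 >= params$rheobase_step
  counts[above] <- pmax(1L, as.integer(round(
    params$fi_slope * (s0[above] - params$rheobase_step + 1))))
  if (any(counts * footprint > n_samp)) {
    stop("gen_current_clamp: ", max(counts), " spikes do not fit in a ",
         protocol$step_duration, " ms step (footprint ",
         round(footprint / fs * 1000, 1), " ms)")
  }

  currents <- step_currents(protocol, params$holding_current)
  thr <- params$threshold_mV
  apex_v <- thr + params$amplitude_mV
  # knot offsets (samples) and voltages relative to the threshold kink
  k_off <- c(-ramp, 0L, t_r, t_r + t_f, t_r + t_f + fahp_off,
             t_r + t_f + fahp_off + rec)

  traces <- matrix(0, protocol$n_steps, n_samp)
  apexes <- vector("list", protocol$n_steps)
  with_seed(seed, {
    for (s in seq_len(protocol$n_steps)) {
      base <- min(params$v_rest +
                    params$depol_gain * (currents[s] - params$holding_current),
                  thr - 5)
      v <- rep(base, n_samp)
      n_sp <- counts[s]
      if (n_sp > 0L) {
        slot <- n_samp %/% n_sp
        onsets <- (seq_len(n_sp) - 1L) * slot + ramp + 1L  # threshold kink
        k_v <- c(base, thr, apex_v, thr, thr - params$fahp5_mV, base)
        for (o in onsets) {
          ki <- o + k_off
          seg <- stats::approx(ki, k_v, xout = ki[1]:ki[length(ki)])$y
          v[ki[1]:ki[length(ki)]] <- seg
        }
        apexes[[s]] <- onsets + t_r
      } else {
        apexes[[s]] <- integer(0)
      }
      if (params$noise_sd > 0) v <- v + stats::rnorm(n_samp, 0, params$noise_sd)
      traces[s, ] <- v
    }
  })

  sweeps <- sweep_set(traces, fs, protocol,
                      holding_current = params$holding_current,
                      capacitance = params$capacitance,
                      cell_id = cell_id, group_id = group_id)
  truth <- list(
    spike_counts = counts,
    apex_samples = apexes,
    rheobase_step = params$rheobase_step,
    template = list(threshold_mV = thr,
                    amplitude_mV = params$amplitude_mV,
                    width_ms = (t_r + t_f) / 2 / fs * 1000,
                    fahp5_mV = params$fahp5_mV),
    params = params)
  list(sweeps = sweeps, truth = truth)
}

#' Parameters for the voltage-clamp current-family generator
#'
#' Voltage-dependent current densities (pA/pF) are supplied as functions of
#' the test potential: an inward (negative) transient sodium term peaking at
#' `na_latency_ms`, an outward fast potassium transient, and an outward slow
#' potassium component that ramps up and then persists to the end of the
#' 400 ms step, so the plateau value is exact by construction.
#'
#' @param na_map,kfast_map,kslow_map functions mV -> pA/pF; `na_map` must be
#'   non-positive, the potassium maps non-negative.
#' @param na_latency_ms time-to-peak of the sodium transient.
#' @param kfast_latency_ms time-to-peak of the fast potassium transient.
#' @param kslow_rise_ms ramp time of the slow potassium component.
#' @param noise_sd additive white noise, pA.
#' @return An object of class `vc_sim_params`.
#' @export
vc_sim_params <- function(
    na_map = function(v) ifelse(v >= -40, -120 * exp(-((v + 10) / 15)^2), 0),
    kfast_map = function(v) ifelse(v > -30, 90 * (v + 30) / 110, 0),
    kslow_map = function(v) ifelse(v > -30, 70 * (v + 30) / 110, 0),
    na_latency_ms = 1.5, kfast_latency_ms = 2, kslow_rise_ms = 50,
    noise_sd = 5) {
  v_chk <- seq(-90, 80, by = 5)
  if (any(na_map(v_chk) > 0)) stop("na_map must be <= 0 (inward current)")
  if (any(kfast_map(v_chk) < 0) || any(kslow_map(v_chk) < 0)) {
    stop("potassium maps must be >= 0 (outward current)")
  }
  structure(as.list(environment())[c("na_map", "kfast_map", "kslow_map",
                                     "na_latency_ms", "kfast_latency_ms",
                                     "kslow_rise_ms", "noise_sd")],
            class = "vc_sim_params")
}

#' Simulate a voltage-clamp sweep family with known current densities
#'
#' @param params a [vc_sim_params()].
#' @param protocol a voltage-clamp [stimulus_protocol()].
#' @param capacitance cell capacitance, pF (scales densities to currents).
#' @param sampling_rate Hz.
#' @param seed integer seed.
#' @param cell_id,group_id identifiers.
#' @return List with `sweeps` (a [sweep_set()] of currents in pA) and
#'   `truth`: per-step test potential and the exact normalized peak sodium,
#'   fast potassium and slow-plateau densities (pA/pF).
#' @export
gen_voltage_clamp <- function(params = vc_sim_params(),
                              protocol = stimulus_protocol("voltage_clamp"),
                              capacitance = 30, sampling_rate = 20000,
                              seed = NULL, cell_id = "sim",
                              group_id = "sim") {
  stopifnot(inherits(params, "vc_sim_params"),
            protocol$mode == "voltage_clamp", capacitance > 0)
  fs <- sampling_rate
  n_samp <- as.integer(round(protocol$step_duration / 1000 * fs))
  tms <- (seq_len(n_samp) - 1L) / fs * 1000     # ms from step onset
  alpha <- function(t, lat) ifelse(t <= 0, 0, (t / lat) * exp(1 - t / lat))
  na_shape <- alpha(tms, params$na_latency_ms)          # peaks at exactly 1
  kf_shape <- alpha(tms, params$kfast_latency_ms)
  ks_shape <- pmin(tms / params$kslow_rise_ms, 1)       # plateau exactly 1

  volts <- step_voltages(protocol)
  na_d <- params$na_map(volts)
  kf_d <- params$kfast_map(volts)
  ks_d <- params$kslow_map(volts)

  traces <- matrix(0, protocol$n_steps, n_samp)
  with_seed(seed, {
    for (s in seq_len(protocol$n_steps)) {
      i <- capacitance * (na_d[s] * na_shape + kf_d[s] * kf_shape +
                            ks_d[s] * ks_shape)
      if (params$noise_sd > 0) i <- i + stats::rnorm(n_samp, 0, params$noise_sd)
      traces[s, ] <- i
    }
  })
  sweeps <- sweep_set(traces, fs, protocol, capacitance = capacitance,
                      cell_id = cell_id, group_id = group_id)
  truth <- data.frame(step = seq_len(protocol$n_steps),
                      test_potential_mV = volts,
                      na_peak = na_d, kfast = kf_d, kslow = ks_d)
  list(sweeps = sweeps, truth = truth)
}

#' Parameters for the spontaneous-EPSC generator
#'
#' Events are a homogeneous Poisson process; each event subtracts a
#' negative-going biexponential kernel (rise `rise_ms`, decay `decay_ms`,
#' peak normalized to the sampled amplitude) from a zero baseline.
#'
#' @param rate Hz.
#' @param amp_mean,amp_sd event amplitude distribution, pA (truncated > 0).
#' @param rise_ms,decay_ms kernel time constants; `decay_ms > rise_ms > 0`.
#' @param duration s.
#' @param noise_sd additive white noise, pA.
#' @param sampling_rate Hz.
#' @return An object of class `epsc_sim_params`.
#' @export
epsc_sim_params <- function(rate = 2, amp_mean = 30, amp_sd = 5,
                            rise_ms = 1, decay_ms = 5, duration = 60,
                            noise_sd = 2, sampling_rate = 20000) {
  stopifnot(rate >= 0, decay_ms > rise_ms, rise_ms > 0, duration > 0,
            amp_mean > 0, amp_sd >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "epsc_sim_params")
}

#' Simulate a gap-free EPSC recording with known event times
#'
#' @param params an [epsc_sim_params()].
#' @param seed integer seed.
#' @return List with `trace` (an [np_trace()], pA) and `truth`: exact event
#'   times (s) and amplitudes (pA).
#' @export
gen_epsc <- function(params = epsc_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "epsc_sim_params"))
  fs <- params$sampling_rate
  n <- as.integer(round(params$duration * fs))
  with_seed(seed, {
    n_ev <- stats::rpois(1, params$rate * params$duration)
    times <- sort(stats::runif(n_ev, 0, params$duration))
    amps <- if (n_ev > 0) {
      a <- stats::rnorm(n_ev, params$amp_mean, params$amp_sd)
      while (any(a <= 0)) a[a <= 0] <- stats::rnorm(sum(a <= 0),
                                                    params$amp_mean,
                                                    params$amp_sd)
      a
    } else numeric(0)
    x <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd)
         else numeric(n)
  })
  if (length(times) > 0) {
    tr <- params$rise_ms / 1000; td <- params$decay_ms / 1000
    klen <- as.integer(round(8 * td * fs))
    kt <- (seq_len(klen) - 1L) / fs
    kern <- exp(-kt / td) - exp(-kt / tr)
    kern <- kern / max(kern)
    for (k in seq_along(times)) {
      i0 <- as.integer(floor(times[k] * fs)) + 1L
      i1 <- min(i0 + klen - 1L, n)
      x[i0:i1] <- x[i0:i1] - amps[k] * kern[seq_len(i1 - i0 + 1L)]
    }
  }
  list(trace = np_trace(x, fs),
       truth = list(times = times, amplitudes = amps,
                    n_events = length(times)))
}
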