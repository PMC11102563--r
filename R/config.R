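#' Stimulus protocol description
#'
#' Describes the step protocol used to acquire a sweep family. The
#' current-clamp default is the 3 pA / 400 ms ladder used for evoked-spike
#' counting: 38 depolarizing steps, the first injected 12 pA below the
#' holding current that keeps the cell at -60 mV. The voltage-clamp default
#' is a 400 ms step family from -90 to +80 mV in 10 mV increments from a
#' -60 mV holding potential, used for sodium/potassium current extraction.
#'
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param n_steps number of steps; defaults to 38 (current clamp) or the
#'   length of the voltage ladder (voltage clamp).
#' @param step_duration step length in ms.
#' @param current_start_offset first step's current relative to the holding
#'   current, pA (current clamp).
#' @param current_increment per-step current increment, pA.
#' @param voltage_min,voltage_max,voltage_increment voltage ladder, mV
#'   (voltage clamp).
#' @param holding_potential command/holding potential, mV.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                              n_steps = NULL,
                              step_duration = 400,
                              current_start_offset = -12,
                              current_increment = 3,
                              voltage_min = -90,
                              voltage_max = 80,
                              voltage_increment = 10,
                              holding_potential = -60) {
  mode <- match.arg(mode)
  if (is.null(n_steps)) {
    n_steps <- if (mode == "current_clamp") {
      38L
    } else {
      as.integer(round((voltage_max - voltage_min) / voltage_increment)) + 1L
    }
  }
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 1L, step_duration > 0)
  structure(
    list(mode = mode,
         n_steps = n_steps,
         step_duration = step_duration,
         current_start_offset = current_start_offset,
         current_increment = current_increment,
         voltage_min = voltage_min,
         voltage_max = voltage_max,
         voltage_increment = voltage_increment,
         holding_potential = holding_potential),
    class = "stimulus_protocol")
}

#' Injected current per step of a current-clamp protocol
#'
#' @param protocol a [stimulus_protocol()] in current-clamp mode.
#' @param holding_current holding current in pA.
#' @return Numeric vector (pA), one entry per step.
#' @export
step_currents <- function(protocol, holding_current = 0) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            protocol$mode == "current_clamp")
  holding_current + protocol$current_start_offset +
    (seq_len(protocol$n_steps) - 1L) * protocol$current_increment
}

#' Test potential per step of a voltage-clamp protocol
#'
#' @param protocol a [stimulus_protocol()] in voltage-clamp mode.
#' @return Numeric vector (mV), one entry per step.
#' @export
step_voltages <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            protocol$mode == "voltage_clamp")
  protocol$voltage_min + (seq_len(protocol$n_steps) - 1L) * protocol$voltage_increment
}

#' Analysis configuration
#'
#' Central container for the pipeline's numeric constants. Defaults encode
#' the published analysis conventions: spikes counted over the first 32
#' (dopaminergic) or 30 (hippocampal) depolarization steps; cells needing
#' more than 50 pA of holding current to sit at -60 mV excluded; fast
#' afterhyperpolarization read 5 ms after the spike returns below threshold;
#' sodium currents compared between -20 and 0 mV and potassium currents
#' between 40 and 80 mV; calcium-imaging neurons flagged when the lag-6
#' normalized fluorescence difference exceeds 0.05 and inactive ROIs when
#' their fluorescence ratio falls below 10% of the most active non-neuron;
#' 35-frame correlation windows, top-10 synchrony averaging, a 0.1 Hz PSD
#' cutoff; network edges at overlap coefficient >= 0.3 with differential
#' expression gated at FDR < 0.05 and |log2FC| > 1.1.
#'
#' @param n_steps_counted depolarization steps entering the evoked-AP total
#'   (32 dopaminergic, 30 hippocampal).
#' @param holding_current_max exclusion bound on |holding current|, pA.
#' @param fahp_delay delay after threshold re-crossing at which the fast
#'   afterhyperpolarization is read, ms.
#' @param na_window,k_window test-potential windows (mV) over which sodium
#'   and potassium currents are statistically compared.
#' @param na_peak_window_ms,fast_k_window time windows from step onset (ms)
#'   searched for the sodium peak and the fast potassium maximum.
#' @param slow_k_tail trailing window (ms) averaged for the slow potassium
#'   current at the end of the step.
#' @param spike spike-detection settings: `detect_level` (mV floor for an
#'   apex), `refractory_ms` (minimum apex separation), `d2_smooth`
#'   (moving-mean width, samples, before the second derivative),
#'   `d2_window_ms` (pre-apex search window for the threshold).
#' @param epsc EPSC detector settings: `threshold_sd` (multiples of the
#'   robust noise SD), `min_interval_ms`, `baseline_window_s` (rolling-median
#'   baseline span).
#' @param calcium calcium-imaging settings; see Details in the vignette.
#' @param network enrichment-network gates: `oc_min`, `fdr_max`,
#'   `log2fc_min`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(n_steps_counted = 32L,
                            holding_current_max = 50,
                            fahp_delay = 5,
                            na_window = c(-20, 0),
                            k_window = c(40, 80),
                            na_peak_window_ms = 10,
                            fast_k_window = 10,
                            slow_k_tail = 5,
                            spike = list(),
                            epsc = list(),
                            calcium = list(),
                            network = list()) {
  spike <- utils::modifyList(
    list(detect_level = -10, refractory_ms = 3, d2_smooth = 5L,
         d2_window_ms = 10),
    spike)
  epsc <- utils::modifyList(
    list(threshold_sd = 3.5, min_interval_ms = 5, baseline_window_s = 1,
         smooth_ms = 0.5),
    epsc)
  calcium <- utils::modifyList(
    list(lag_frames = 6L, neuron_threshold = 0.05, inactive_fraction = 0.10,
         corr_window_frames = 35L, ma_frames = 5L, top_k = 10L,
         psd_high_cutoff_hz = 0.1, psd_nfft = 256L, n_top_astrocytes = 3L,
         prominence_fraction = 0.2, min_event_sep_frames = 5L),
    calcium)
  network <- utils::modifyList(
    list(oc_min = 0.3, fdr_max = 0.05, log2fc_min = 1.1),
    network)
  cfg <- list(n_steps_counted = as.integer(n_steps_counted),
              holding_current_max = holding_current_max,
              fahp_delay = fahp_delay,
              na_window = na_window,
              k_window = k_window,
              na_peak_window_ms = na_peak_window_ms,
              fast_k_window = fast_k_window,
              slow_k_tail = slow_k_tail,
              spike = spike, epsc = epsc, calcium = calcium,
              network = network)
  pos <- c(cfg$holding_current_max, cfg$fahp_delay, cfg$na_peak_window_ms,
           cfg$fast_k_window, cfg$slow_k_tail, spike$refractory_ms,
           epsc$threshold_sd, epsc$min_interval_ms, epsc$baseline_window_s,
           calcium$neuron_threshold, calcium$inactive_fraction,
           calcium$psd_high_cutoff_hz, calcium$prominence_fraction,
           network$oc_min, network$fdr_max, network$log2fc_min)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all analysis_config thresholds must be strictly positive")
  }
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  evoked APs: first", x$n_steps_counted, "steps; exclude |holding| >",
      x$holding_current_max, "pA\n")
  cat("  IV windows: Na", paste(x$na_window, collapse = ".."), "mV; K",
      paste(x$k_window, collapse = ".."), "mV\n")
  cat("  calcium: lag", x$calcium$lag_frames, "threshold",
      x$calcium$neuron_threshold, "; network: OC >=", x$network$oc_min, "\n")
  invisible(x)
}
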