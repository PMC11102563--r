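#' Sweep family from a step protocol
#'
#' A stimulus-aligned stack of recorded traces, one row per protocol step.
#' Rows hold membrane potential (mV, current clamp) or current (pA, voltage
#' clamp) sampled at `sampling_rate`; each sweep spans exactly the step
#' window, so `n_samples / sampling_rate` equals the step duration.
#'
#' @param traces numeric matrix, `n_steps x n_samples`.
#' @param sampling_rate Hz.
#' @param protocol a [stimulus_protocol()].
#' @param holding_current pA (current clamp).
#' @param capacitance cell capacitance, pF; required > 0 for voltage-clamp
#'   normalization.
#' @param cell_id,group_id identifiers carried through to reports.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(traces, sampling_rate, protocol,
                      holding_current = 0, capacitance = NA_real_,
                      cell_id = "cell", group_id = "group") {
  traces <- as.matrix(traces)
  stopifnot(is.numeric(traces), sampling_rate > 0,
            inherits(protocol, "stimulus_protocol"))
  if (nrow(traces) != protocol$n_steps) {
    stop("sweep_set: ", nrow(traces), " traces but protocol declares ",
         protocol$n_steps, " steps")
  }
  if (!all(is.finite(traces))) stop("sweep_set: non-finite samples")
  if (protocol$mode == "voltage_clamp" &&
      (!is.na(capacitance) && capacitance <= 0)) {
    stop("sweep_set: capacitance must be > 0 for voltage-clamp normalization")
  }
  structure(
    list(traces = traces, sampling_rate = sampling_rate, protocol = protocol,
         holding_current = holding_current, capacitance = capacitance,
         cell_id = cell_id, group_id = group_id),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s | %s | %d sweeps x %d samples @ %g kHz\n",
              x$cell_id, x$protocol$mode, nrow(x$traces), ncol(x$traces),
              x$sampling_rate / 1000))
  invisible(x)
}

#' Gap-free single trace
#'
#' A continuous recording (for spontaneous synaptic activity, pA).
#'
#' @param samples numeric vector.
#' @param sampling_rate Hz.
#' @return An object of class `np_trace` with `duration` in seconds.
#' @export
np_trace <- function(samples, sampling_rate) {
  stopifnot(is.numeric(samples), length(samples) >= 2, sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 duration = length(samples) / sampling_rate),
            class = "np_trace")
}

#' @export
print.np_trace <- function(x, ...) {
  cat(sprintf("<np_trace> %g s @ %g kHz (%d samples)\n", x$duration,
              x$sampling_rate / 1000, length(x$samples)))
  invisible(x)
}

#' ROI fluorescence matrix
#'
#' ROI-by-frame fluorescence from a calcium-imaging video; typical
#' recordings are 1800 frames at ~10 Hz. Frame index is 0-based in time:
#' time of frame k is `k / frame_rate` seconds.
#'
#' @param F numeric matrix, `n_roi x n_frames`, fluorescence (a.u.).
#' @param frame_rate Hz.
#' @param roi_ids ROI identifiers (defaults to row indices).
#' @return An object of class `fluor_matrix`.
#' @export
fluor_matrix <- function(F, frame_rate = 10, roi_ids = NULL) {
  F <- as.matrix(F)
  stopifnot(is.numeric(F), frame_rate > 0, ncol(F) >= 2)
  if (!all(is.finite(F))) stop("fluor_matrix: non-finite fluorescence values")
  if (is.null(roi_ids)) roi_ids <- seq_len(nrow(F))
  stopifnot(length(roi_ids) == nrow(F))
  rownames(F) <- as.character(roi_ids)
  structure(list(F = F, frame_rate = frame_rate, roi_ids = roi_ids),
            class = "fluor_matrix")
}

#' @export
print.fluor_matrix <- function(x, ...) {
  cat(sprintf("<fluor_matrix> %d ROIs x %d frames @ %g Hz\n",
              nrow(x$F), ncol(x$F), x$frame_rate))
  invisible(x)
}
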