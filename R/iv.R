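#' Capacitance-normalized IV table from a voltage-clamp sweep family
#'
#' Per step: the sodium peak is the minimum current within
#' `na_peak_window_ms` of step onset (clipped at <= 0, inward negative); the
#' fast potassium current is the maximal outgoing current right after the
#' depolarization step, within `fast_k_window` ms of onset; the slow
#' potassium current is the current at the end of the 400 ms depolarization
#' phase, averaged over the final `slow_k_tail` ms for noise robustness. All
#' three are normalized by the cell capacitance (pA/pF).
#'
#' @param sweeps a voltage-clamp [sweep_set()] with `capacitance > 0`.
#' @param cfg an [analysis_config()].
#' @return data.frame of class `iv_table`: `step`, `test_potential_mV`,
#'   `na_peak`, `kfast`, `kslow` (pA/pF).
#' @export
extract_iv <- function(sweeps, cfg = analysis_config()) {
  stopifnot(inherits(sweeps, "sweep_set"),
            sweeps$protocol$mode == "voltage_clamp")
  C <- sweeps$capacitance
  if (is.na(C) || C <= 0) stop("extract_iv: capacitance must be > 0")
  fs <- sweeps$sampling_rate
  n <- ncol(sweeps$traces)
  i_na <- seq_len(min(n, max(1L, round(cfg$na_peak_window_ms / 1000 * fs))))
  i_kf <- seq_len(min(n, max(1L, round(cfg$fast_k_window / 1000 * fs))))
  n_tail <- min(n, max(1L, round(cfg$slow_k_tail / 1000 * fs)))
  i_ks <- (n - n_tail + 1L):n

  volts <- step_voltages(sweeps$protocol)
  out <- data.frame(
    step = seq_len(nrow(sweeps$traces)),
    test_potential_mV = volts,
    na_peak = vapply(seq_len(nrow(sweeps$traces)), function(s)
      min(min(sweeps$traces[s, i_na]) / C, 0), numeric(1)),
    kfast = vapply(seq_len(nrow(sweeps$traces)), function(s)
      max(sweeps$traces[s, i_kf]) / C, numeric(1)),
    kslow = vapply(seq_len(nrow(sweeps$traces)), function(s)
      mean(sweeps$traces[s, i_ks]) / C, numeric(1)))
  class(out) <- c("iv_table", class(out))
  out
}

#' Group comparison of windowed IV currents
#'
#' Restricts each cell's IV table to the physiological comparison windows
#' (-20..0 mV for sodium, 40..80 mV for potassium), then compares groups by
#' one-way ANOVA per current type on the per-cell mean over the window.
#' Sodium currents are compared as signed values (more negative = larger
#' inward current).
#'
#' @param tables named list of [extract_iv()] tables, one per cell.
#' @param groups character vector of group labels aligned with `tables`.
#' @param cfg an [analysis_config()].
#' @return List with `tests` (data.frame: current type, F, p), `cell_means`
#'   (per cell and current type), and `potential_means` (group mean +/- SE
#'   per retained test potential and current type).
#' @export
iv_window_stats <- function(tables, groups, cfg = analysis_config()) {
  stopifnot(length(tables) == length(groups), length(tables) >= 2)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("iv_window_stats: need >= 2 groups")
  if (any(table(groups) < 2)) stop("iv_window_stats: need >= 2 cells per group")

  windows <- list(na_peak = cfg$na_window, kfast = cfg$k_window,
                  kslow = cfg$k_window)
  cell_means <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    row <- lapply(names(windows), function(ct) {
      w <- windows[[ct]]
      keep <- tb$test_potential_mV >= w[1] & tb$test_potential_mV <= w[2]
      if (!any(keep)) stop("iv_window_stats: empty ", ct, " window [",
                           w[1], ",", w[2], "] mV")
      mean(tb[[ct]][keep])
    })
    names(row) <- names(windows)
    data.frame(cell = i, group = groups[i], row)
  }))

  tests <- do.call(rbind, lapply(names(windows), function(ct) {
    cmp <- anova_oneway(split(cell_means[[ct]], cell_means$group))
    data.frame(current = ct, statistic = cmp$statistic, p_value = cmp$p_value)
  }))

  potential_means <- do.call(rbind, lapply(names(windows), function(ct) {
    w <- windows[[ct]]
    do.call(rbind, lapply(unique(groups), function(g) {
      tbs <- tables[groups == g]
      vals <- sapply(tbs, function(tb) {
        keep <- tb$test_potential_mV >= w[1] & tb$test_potential_mV <= w[2]
        stats::setNames(tb[[ct]][keep], tb$test_potential_mV[keep])
      })
      vals <- as.matrix(vals)  # potentials x cells
      data.frame(current = ct, group = g,
                 test_potential_mV = as.numeric(rownames(vals)),
                 mean = rowMeans(vals),
                 se = apply(vals, 1, stats::sd) / sqrt(ncol(vals)))
    }))
  }))
  rownames(potential_means) <- NULL
  list(tests = tests, cell_means = cell_means,
       potential_means = potential_means)
}
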