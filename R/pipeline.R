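#' Run the full per-cell analysis pipeline from a manifest
#'
#' The manifest is a CSV (or data.frame) with columns `cell_id`, `group`,
#' `modality` and `path`, one row per recording. Modalities:
#' `current_clamp` (sweep bundle; evoked-AP count + rheobase-spike shape),
#' `voltage_clamp` (sweep bundle; capacitance-normalized IV table),
#' `epsc` (gap-free trace bundle; synaptic event statistics), and
#' `calcium` (ROI fluorescence bundle; classification, event rates,
#' astrocyte summary, synchrony, PSD ratio). Group comparisons use the
#' two-sample t test for per-cell scalars and one-way ANOVA for windowed
#' IV currents; pooled EPSC amplitudes are exported as per-group ECDFs.
#'
#' The analysis path is deterministic: identical manifest, configuration
#' and seed produce byte-identical tables.
#'
#' @param manifest CSV path or data.frame.
#' @param out_dir output directory for the report bundle.
#' @param cfg an [analysis_config()].
#' @param seed integer; recorded in the log and used for any stochastic
#'   step (the analysis itself is deterministic).
#' @return Invisibly, a list with the per-cell feature table, the
#'   comparison table, calcium summaries and the per-stage log.
#' @export
run_pipeline <- function(manifest, out_dir, cfg = analysis_config(),
                         seed = 1L) {
  man <- if (is.character(manifest)) {
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    as.data.frame(manifest)
  }
  if (nrow(man) == 0) stop("run_pipeline: empty manifest")
  need <- c("cell_id", "group", "modality", "path")
  if (!all(need %in% names(man))) {
    stop("run_pipeline: manifest needs columns ",
         paste(need, collapse = ", "))
  }
  known <- c("current_clamp", "voltage_clamp", "epsc", "calcium")
  bad <- setdiff(unique(man$modality), known)
  if (length(bad)) stop("run_pipeline: unknown modality '", bad[1], "'")
  groups <- unique(man$group)
  for (g in groups) {
    if (sum(man$group == g) == 0) stop("run_pipeline: empty group '", g, "'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  log <- list(seed = seed, groups = groups, stages = list())
  comparisons <- list()

  add_cmp <- function(analyte, cmp) {
    comparisons[[length(comparisons) + 1L]] <<- data.frame(
      analyte = analyte, test = cmp$test_name,
      groups = paste(cmp$groups$group, collapse = "|"),
      n = paste(cmp$groups$n, collapse = "|"),
      statistic = cmp$statistic, p_value = cmp$p_value)
  }
  compare_scalar <- function(df, col) {
    by_g <- split(df[[col]], df$group)
    by_g <- lapply(by_g, function(v) v[is.finite(v)])
    by_g <- by_g[lengths(by_g) >= 2]
    if (length(by_g) == 2) {
      do.call(two_sample_t, unname(by_g))
    } else if (length(by_g) > 2) {
      anova_oneway(by_g)
    } else NULL
  }

  cells <- data.frame(cell_id = unique(man$cell_id))
  cells$group <- man$group[match(cells$cell_id, man$cell_id)]

  ## -- current clamp -------------------------------------------------
  cc <- man[man$modality == "current_clamp", ]
  if (nrow(cc)) {
    feats <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
      ss <- read_sweepset(cc$path[i])
      ev <- count_evoked_aps(ss, cfg)
      row <- data.frame(cell_id = cc$cell_id[i], group = cc$group[i],
                        total_aps = ev$total, excluded = ev$excluded,
                        reason = ev$reason, capacitance = ss$capacitance,
                        threshold_mV = NA_real_, amplitude_mV = NA_real_,
                        width_ms = NA_real_, fahp5_mV = NA_real_)
      if (!ev$excluded && ev$total > 0) {
        sh <- spike_shape(ss, cfg)
        row$threshold_mV <- sh$threshold_mV
        row$amplitude_mV <- sh$amplitude_mV
        row$width_ms <- sh$width_ms
        row$fahp5_mV <- sh$fahp5_mV
      }
      row
    }))
    utils::write.table(feats, file.path(out_dir, "ephys_evoked_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ok <- feats[!feats$excluded, ]
    for (col in c("total_aps", "threshold_mV", "amplitude_mV", "width_ms",
                  "fahp5_mV", "capacitance")) {
      cmp <- compare_scalar(ok, col)
      if (!is.null(cmp)) add_cmp(col, cmp)
    }
    log$stages$current_clamp <- list(
      n_cells = nrow(feats), n_excluded = sum(feats$excluded),
      exclusion_reasons = as.list(table(feats$reason[feats$excluded])))
  }

  ## -- voltage clamp -------------------------------------------------
  vc <- man[man$modality == "voltage_clamp", ]
  if (nrow(vc)) {
    tables <- lapply(vc$path, function(p) extract_iv(read_sweepset(p), cfg))
    iv_rows <- do.call(rbind, lapply(seq_along(tables), function(i) {
      cbind(cell_id = vc$cell_id[i], group = vc$group[i], tables[[i]])
    }))
    utils::write.table(iv_rows, file.path(out_dir, "iv_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(unique(vc$group)) >= 2 && all(table(vc$group) >= 2)) {
      ws <- iv_window_stats(tables, vc$group, cfg)
      for (i in seq_len(nrow(ws$tests))) {
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          analyte = paste0("iv_", ws$tests$current[i]),
          test = "anova_oneway",
          groups = paste(unique(vc$group), collapse = "|"),
          n = paste(table(vc$group)[unique(vc$group)], collapse = "|"),
          statistic = ws$tests$statistic[i], p_value = ws$tests$p_value[i])
      }
      utils::write.table(ws$potential_means,
                         file.path(out_dir, "iv_window_means.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log$stages$voltage_clamp <- list(n_cells = nrow(vc), n_excluded = 0L)
  }

  ## -- EPSC ----------------------------------------------------------
  ep <- man[man$modality == "epsc", ]
  if (nrow(ep)) {
    sums <- lapply(ep$path, function(p) detect_epscs(read_trace(p), cfg))
    edf <- data.frame(cell_id = ep$cell_id, group = ep$group,
                      n_events = vapply(sums, `[[`, integer(1), "n_events"),
                      rate_hz = vapply(sums, `[[`, numeric(1), "rate_hz"),
                      mean_amplitude_pA = vapply(sums, `[[`, numeric(1),
                                                 "mean_amplitude_pA"))
    utils::write.table(edf, file.path(out_dir, "epsc_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (col in c("rate_hz", "mean_amplitude_pA")) {
      cmp <- compare_scalar(edf, col)
      if (!is.null(cmp)) add_cmp(paste0("epsc_", col), cmp)
    }
    pooled <- lapply(split(seq_len(nrow(ep)), ep$group), function(idx) {
      unlist(lapply(sums[idx], `[[`, "amplitudes"))
    })
    pooled <- pooled[lengths(pooled) > 0]
    if (length(pooled)) {
      curves <- pooled_ecdf(pooled)
      for (g in names(curves)) {
        utils::write.table(ecdf_table(curves[[g]]),
                           file.path(out_dir, paste0("epsc_ecdf_", g, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    log$stages$epsc <- list(n_cells = nrow(ep),
                            n_silent = sum(edf$n_events == 0))
  }

  ## -- calcium -------------------------------------------------------
  ca <- man[man$modality == "calcium", ]
  if (nrow(ca)) {
    summaries <- lapply(seq_len(nrow(ca)), function(i) {
      fl <- read_fluor(ca$path[i])
      cls <- classify_rois(fl, cfg)
      neurons <- which(cls$label == "active_neuron")
      rates <- vapply(neurons, function(r)
        count_neuron_events(fl$F[r, ], fl$frame_rate, cfg)$rate_hz,
        numeric(1))
      astro <- astrocyte_summary(cls, cfg)
      syn <- if (length(neurons) >= 2) {
        synchrony(fluor_matrix(fl$F[neurons, , drop = FALSE],
                               fl$frame_rate), cfg)
      } else NULL
      psd <- if (length(neurons) >= 1) {
        psd_ratio(fluor_matrix(fl$F[neurons, , drop = FALSE],
                               fl$frame_rate), cfg = cfg)
      } else NULL
      roi_tab <- cbind(cell_id = ca$cell_id[i], group = ca$group[i], cls)
      list(cell_id = ca$cell_id[i], group = ca$group[i], rois = roi_tab,
           n_neurons = length(neurons),
           n_astrocytes = sum(cls$label == "active_astrocyte"),
           n_inactive = sum(cls$label == "inactive"),
           mean_neuron_rate_hz = if (length(rates)) mean(rates) else NA_real_,
           astro_mean_ratio = astro$mean_ratio,
           synchrony_top_k_norm = if (is.null(syn)) NA_real_
                                  else syn$top_k_mean_norm,
           psd_ratio_top_k = if (is.null(psd)) NA_real_ else psd$top_k_mean)
    })
    roi_all <- do.call(rbind, lapply(summaries, `[[`, "rois"))
    utils::write.table(roi_all, file.path(out_dir, "calcium_rois.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cdf <- do.call(rbind, lapply(summaries, function(s) {
      data.frame(cell_id = s$cell_id, group = s$group,
                 n_neurons = s$n_neurons, n_astrocytes = s$n_astrocytes,
                 n_inactive = s$n_inactive,
                 mean_neuron_rate_hz = s$mean_neuron_rate_hz,
                 astro_mean_ratio = s$astro_mean_ratio,
                 synchrony_top_k_norm = s$synchrony_top_k_norm,
                 psd_ratio_top_k = s$psd_ratio_top_k)
    }))
    utils::write.table(cdf, file.path(out_dir, "calcium_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (col in c("mean_neuron_rate_hz", "astro_mean_ratio",
                  "synchrony_top_k_norm", "psd_ratio_top_k")) {
      cmp <- compare_scalar(cdf, col)
      if (!is.null(cmp)) add_cmp(paste0("calcium_", col), cmp)
    }
    log$stages$calcium <- list(n_recordings = nrow(ca))
  }

  cmp_tab <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(analyte = character(0), test = character(0),
               groups = character(0), n = character(0),
               statistic = numeric(0), p_value = numeric(0))
  utils::write.table(cmp_tab, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(comparisons = cmp_tab, log = log, out_dir = out_dir))
}
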