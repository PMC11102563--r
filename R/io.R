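#' Write a sweep family to the native csv-bundle layout
#'
#' One directory per cell: `traces.csv` (wide, one column per sweep,
#' full-precision text so round-trips are bit-exact) plus `meta.json`
#' (sampling rate, protocol, holding current, capacitance, identifiers).
#'
#' @param sweeps a [sweep_set()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sweepset <- function(sweeps, dir) {
  stopifnot(inherits(sweeps, "sweep_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- t(sweeps$traces)
  colnames(tr) <- sprintf("sweep_%02d", seq_len(ncol(tr)))
  txt <- apply(tr, 2, function(col) sprintf("%.17g", col))
  utils::write.table(txt, file.path(dir, "traces.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  meta <- list(sampling_rate = sweeps$sampling_rate,
               holding_current = sweeps$holding_current,
               capacitance = sweeps$capacitance,
               cell_id = sweeps$cell_id, group_id = sweeps$group_id,
               protocol = unclass(sweeps$protocol))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a sweep family
#'
#' The native interchange format is a csv bundle (see [write_sweepset()]).
#' HDF5 containers and Axon ABF files are not supported by this build and
#' raise an informative error.
#'
#' @param path bundle directory.
#' @param format `"csv_bundle"`.
#' @return A [sweep_set()].
#' @export
read_sweepset <- function(path, format = c("csv_bundle", "hdf5_container",
                                           "abf")) {
  format <- match.arg(format)
  if (format != "csv_bundle") {
    stop("read_sweepset: format '", format, "' is not supported; ",
         "convert to the csv_bundle layout")
  }
  f_tr <- file.path(path, "traces.csv")
  f_meta <- file.path(path, "meta.json")
  if (!file.exists(f_tr) || !file.exists(f_meta)) {
    stop("read_sweepset: bundle at '", path,
         "' must contain traces.csv and meta.json")
  }
  meta <- jsonlite::read_json(f_meta, simplifyVector = TRUE)
  for (fld in c("sampling_rate", "protocol")) {
    if (is.null(meta[[fld]])) {
      stop("read_sweepset: meta.json missing required field '", fld, "'")
    }
  }
  pr <- meta$protocol
  if (is.null(pr$mode) || is.null(pr$n_steps)) {
    stop("read_sweepset: meta.json protocol missing required field '",
         if (is.null(pr$mode)) "mode" else "n_steps", "'")
  }
  tr <- as.matrix(utils::read.csv(f_tr, check.names = FALSE))
  storage.mode(tr) <- "double"
  if (any(is.na(tr))) stop("read_sweepset: ragged or non-numeric traces.csv")
  if (ncol(tr) != pr$n_steps) {
    stop("read_sweepset: traces.csv has ", ncol(tr),
         " sweeps but protocol declares ", pr$n_steps)
  }
  # step duration is implied by the sweep length when absent
  step_duration <- pr$step_duration
  if (is.null(step_duration)) {
    step_duration <- nrow(tr) / meta$sampling_rate * 1000
  }
  protocol <- stimulus_protocol(
    mode = pr$mode, n_steps = pr$n_steps, step_duration = step_duration,
    current_start_offset = pr$current_start_offset %||% -12,
    current_increment = pr$current_increment %||% 3,
    voltage_min = pr$voltage_min %||% -90,
    voltage_max = pr$voltage_max %||% 80,
    voltage_increment = pr$voltage_increment %||% 10,
    holding_potential = pr$holding_potential %||% -60)
  sweep_set(t(tr), meta$sampling_rate, protocol,
            holding_current = meta$holding_current %||% 0,
            capacitance = meta$capacitance %||% NA_real_,
            cell_id = meta$cell_id %||% basename(path),
            group_id = meta$group_id %||% "group")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Extract ROI fluorescence traces from a TIFF stack
#'
#' `F[i, t]` is the mean pixel intensity of ROI `i` in frame `t`. ROIs are
#' given as a label image (0 = background, k = ROI k) stored as JSON:
#' an object with `labels` (row-major 2D integer array matching the frame
#' dimensions) and optionally `n_rois` declaring how many ROIs must be
#' present.
#'
#' @param stack_path multi-frame TIFF path.
#' @param roi_path label-mask JSON path.
#' @param frame_rate Hz.
#' @return A [fluor_matrix()].
#' @export
read_fluor_stack <- function(stack_path, roi_path, frame_rate = 10) {
  frames <- tiff::readTIFF(stack_path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  mask_doc <- jsonlite::read_json(roi_path, simplifyVector = TRUE)
  mask <- as.matrix(mask_doc$labels)
  if (!all(dim(frames[[1]]) == dim(mask))) {
    stop("read_fluor_stack: ROI mask is ", paste(dim(mask), collapse = "x"),
         " but frames are ", paste(dim(frames[[1]]), collapse = "x"))
  }
  n_rois <- mask_doc$n_rois %||% max(mask)
  if (n_rois < 1) stop("read_fluor_stack: need at least one ROI")
  idx <- lapply(seq_len(n_rois), function(k) which(mask == k))
  empty <- which(lengths(idx) == 0)
  if (length(empty)) {
    stop("read_fluor_stack: ROI ", paste(empty, collapse = ", "),
         " covers zero pixels")
  }
  F <- vapply(frames, function(fr) {
    vapply(idx, function(px) mean(fr[px]), numeric(1))
  }, numeric(n_rois))
  if (n_rois == 1L) F <- matrix(F, nrow = 1L)
  fluor_matrix(F, frame_rate = frame_rate, roi_ids = seq_len(n_rois))
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set id, description, then member genes.
#'
#' @param path GMT path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to
#'   the set name).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with columns `gene_id`, `log2fc`, `fdr`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_deg_table <- function(path) {
  deg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  missing <- setdiff(need, names(deg))
  if (length(missing)) {
    stop("read_deg_table: missing column(s) ", paste(missing, collapse = ", "))
  }
  deg
}

#' Write / read a gap-free trace bundle
#'
#' Directory with `trace.csv` (single `current_pA` column, full precision)
#' and `meta.json` (`sampling_rate`).
#'
#' @param trace an [np_trace()].
#' @param dir bundle directory.
#' @return Invisibly `dir`; `read_trace()` returns an [np_trace()].
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "np_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("current_pA", sprintf("%.17g", trace$samples)),
             file.path(dir, "trace.csv"))
  jsonlite::write_json(list(sampling_rate = trace$sampling_rate),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_trace
#' @export
read_trace <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) {
    stop("read_trace: meta.json missing required field 'sampling_rate'")
  }
  x <- utils::read.csv(file.path(dir, "trace.csv"))
  np_trace(x$current_pA, meta$sampling_rate)
}

#' Write / read an ROI fluorescence bundle
#'
#' Directory with `fluor.csv` (one row per ROI, one column per frame) and
#' `meta.json` (`frame_rate`, `roi_ids`).
#'
#' @param fluor a [fluor_matrix()].
#' @param dir bundle directory.
#' @return Invisibly `dir`; `read_fluor()` returns a [fluor_matrix()].
#' @export
write_fluor <- function(fluor, dir) {
  stopifnot(inherits(fluor, "fluor_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txt <- apply(fluor$F, c(1, 2), function(v) sprintf("%.17g", v))
  utils::write.table(txt, file.path(dir, "fluor.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(frame_rate = fluor$frame_rate,
                            roi_ids = fluor$roi_ids),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_fluor
#' @export
read_fluor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$frame_rate)) {
    stop("read_fluor: meta.json missing required field 'frame_rate'")
  }
  F <- as.matrix(utils::read.csv(file.path(dir, "fluor.csv"),
                                 header = FALSE))
  storage.mode(F) <- "double"
  fluor_matrix(F, frame_rate = meta$frame_rate,
               roi_ids = meta$roi_ids %||% seq_len(nrow(F)))
}
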