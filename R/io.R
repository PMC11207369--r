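#' Read and write sweep series
#'
#' A sweep series is persisted as two plain-text array files
#' (`<prefix>_amplitude.csv`, `<prefix>_phase.csv`; one row per frame, no
#' header) plus a JSON metadata sidecar (`<prefix>_meta.json`) holding the
#' radar configuration fields and both axes.
#'
#' @param sweeps A [sweep_series()].
#' @param prefix Path prefix for the three files.
#' @param config Optional [radar_config()] stored in the sidecar.
#' @return `write_sweeps()` returns the prefix invisibly; `read_sweeps()`
#'   returns a [sweep_series()].
#' @export
write_sweeps <- function(sweeps, prefix, config = NULL) {
  if (!inherits(sweeps, "sweep_series")) stop("`sweeps` must be a sweep_series", call. = FALSE)
  utils::write.table(sweeps$amplitude, paste0(prefix, "_amplitude.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(sweeps$phase, paste0(prefix, "_phase.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(time = sweeps$time, range = sweeps$range)
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(prefix) {
  amp <- as.matrix(utils::read.table(paste0(prefix, "_amplitude.csv"),
                                     sep = ",", header = FALSE))
  ph <- as.matrix(utils::read.table(paste0(prefix, "_phase.csv"),
                                    sep = ",", header = FALSE))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  dimnames(amp) <- dimnames(ph) <- NULL
  sweep_series(amp, ph, meta$time, meta$range)
}

#' Read and write displacement traces as CSV
#'
#' Columns `time_s`, `displacement_mm`.
#'
#' @param trace A [displacement_trace()].
#' @param path CSV path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a [displacement_trace()].
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "displacement_trace")) stop("`trace` must be a displacement_trace", call. = FALSE)
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              displacement_mm = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  dt <- stats::median(diff(df$time_s))
  displacement_trace(df$displacement_mm, sampling_interval = dt,
                     start_time = df$time_s[1L])
}

#' Read and write activity annotations as CSV
#'
#' Columns `start_s`, `end_s`, `label`.
#'
#' @param annotation An [activity_annotation()].
#' @param path CSV path.
#' @return `write_annotation()` returns `path` invisibly;
#'   `read_annotation()` returns an [activity_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  if (!inherits(annotation, "activity_annotation")) stop("`annotation` must be an activity_annotation", call. = FALSE)
  utils::write.csv(annotation$intervals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  activity_annotation(utils::read.csv(path))
}

#' Write a designed-feature table as CSV
#'
#' Header `subject,start_s,label,range_01..range_10,ac_01..ac_10,
#' fft_01..fft_10,hist_01..hist_10`.
#'
#' @param feature_table A [designed_feature_table()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(feature_table, path) {
  utils::write.csv(feature_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
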