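#' Slice a displacement trace into sliding windows
#'
#' Fixed-length windows (default 4 s = 400 frames at the 0.01 s frame
#' interval) slid by a fixed stride (default 1 s = 100 frames).  A trailing
#' partial window is discarded; a trace shorter than one window yields an
#' empty window set with a warning.
#'
#' @param trace A [displacement_trace()].
#' @param window_s Window length, seconds.
#' @param stride_s Stride between window starts, seconds.
#' @return An object of class `window_set`: a list with `values` (one row
#'   per window), `start_s`, `window_s`, and `sampling_interval`.
#' @examples
#' tr <- displacement_trace(sin(2 * pi * (0:999) / 400), 0.01)
#' nrow(slide_windows(tr)$values) # floor((1000 - 400) / 100) + 1 = 7
#' @export
slide_windows <- function(trace, window_s = 4, stride_s = 1) {
  if (!inherits(trace, "displacement_trace")) {
    stop("`trace` must be a displacement_trace", call. = FALSE)
  }
  dt <- trace$sampling_interval
  W <- round(window_s / dt)
  S <- round(stride_s / dt)
  if (W < 2L || S < 1L) stop("window and stride must span >= 2 and >= 1 samples", call. = FALSE)
  N <- length(trace$values)
  if (N < W) {
    warning("trace shorter than one window; no windows extracted")
    return(structure(list(values = matrix(numeric(0), nrow = 0, ncol = W),
                          start_s = numeric(0), window_s = window_s,
                          sampling_interval = dt),
                     class = "window_set"))
  }
  n_win <- (N - W) %/% S + 1L
  starts <- (seq_len(n_win) - 1L) * S
  vals <- matrix(0, nrow = n_win, ncol = W)
  for (i in seq_len(n_win)) {
    vals[i, ] <- trace$values[(starts[i] + 1L):(starts[i] + W)]
  }
  structure(list(values = vals,
                 start_s = trace$start_time + starts * dt,
                 window_s = window_s, sampling_interval = dt),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (%d samples)\n",
              nrow(x$values), x$window_s, ncol(x$values)))
  invisible(x)
}

#' Label a window from the activity annotation
#'
#' The ground-truth label of a window is the activity at the window's
#' midpoint -- except when a swallow interval is *contained* in the window
#' (both its start and its end fall inside), in which case the window is
#' labelled `"swal"` regardless of the midpoint.  The midpoint of an
#' even-length window is the sample at index `W/2`, i.e. the time
#' `start + window_s / 2`.  A midpoint covered by no annotated interval
#' gives `NA` (the window is excluded from datasets).
#'
#' @param start_s Window start time(s), seconds (vectorised).
#' @param window_s Window length, seconds.
#' @param annotation An [activity_annotation()].
#' @return Character vector of labels (`"resp"`, `"hold"`, `"swal"`, or
#'   `NA`).
#' @export
label_window <- function(start_s, window_s, annotation) {
  if (!inherits(annotation, "activity_annotation")) {
    stop("`annotation` must be an activity_annotation", call. = FALSE)
  }
  iv <- annotation$intervals
  sw <- iv[iv$label == "swal", , drop = FALSE]
  end_s <- start_s + window_s
  mid <- start_s + window_s / 2
  out <- rep(NA_character_, length(start_s))
  eps <- 1e-9
  for (k in seq_along(start_s)) {
    contained <- nrow(sw) > 0L &&
      any(sw$start_s >= start_s[k] - eps & sw$end_s <= end_s[k] + eps)
    if (contained) {
      out[k] <- "swal"
    } else {
      hit <- which(iv$start_s - eps <= mid[k] & mid[k] < iv$end_s - eps)
      if (length(hit)) out[k] <- iv$label[hit[1L]]
    }
  }
  out
}

#' Build a pooled window dataset from recordings
#'
#' Slides windows over every recording, labels them by the midpoint /
#' contained-swallow rule, drops windows whose midpoint no annotated
#' interval covers, and pools the rest with their subject identifiers so
#' grouped (per-subject) cross-validation stays possible downstream.
#'
#' @param recordings A list of recordings, each a list with elements
#'   `trace` (a [displacement_trace()]), `annotation` (an
#'   [activity_annotation()]), and `subject` (an identifier).
#' @param window_s,stride_s Passed to [slide_windows()].
#' @return An object of class `window_dataset`: `values` (windows x samples
#'   matrix), `meta` (data frame with `subject`, `start_s`, `label`),
#'   `window_s`, `sampling_interval`, and attributes `n_excluded` /
#'   `class_counts`.
#' @export
build_dataset <- function(recordings, window_s = 4, stride_s = 1) {
  if (length(recordings) < 1L) stop("need at least one recording", call. = FALSE)
  vals <- list(); metas <- list(); excluded <- 0L
  for (rec in recordings) {
    ws <- slide_windows(rec$trace, window_s, stride_s)
    if (nrow(ws$values) == 0L) next
    lab <- label_window(ws$start_s, window_s, rec$annotation)
    keep <- !is.na(lab)
    excluded <- excluded + sum(!keep)
    if (!any(keep)) next
    vals[[length(vals) + 1L]] <- ws$values[keep, , drop = FALSE]
    metas[[length(metas) + 1L]] <- data.frame(
      subject = as.character(rec$subject),
      start_s = ws$start_s[keep],
      label = lab[keep])
  }
  if (!length(vals)) stop("no labelled windows in any recording", call. = FALSE)
  values <- do.call(rbind, vals)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, window_s = window_s,
                 sampling_interval = recordings[[1L]]$trace$sampling_interval),
            class = "window_dataset",
            n_excluded = excluded,
            class_counts = table(factor(meta$label,
                                        levels = c("resp", "hold", "swal"))))
}

#' @export
print.window_dataset <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat(sprintf("<window_dataset> %d windows of %g s from %d subjects (%s; %d unlabelled excluded)\n",
              nrow(x$values), x$window_s, length(unique(x$meta$subject)),
              paste(names(cc), cc, sep = ":", collapse = ", "),
              attr(x, "n_excluded")))
  invisible(x)
}
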