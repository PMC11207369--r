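#' Radar acquisition configuration
#'
#' Describes the pulse-coherent radar used for chest measurement: carrier
#' frequency, frame (sweep) interval, and the sampled range axis.  Defaults
#' match a 60 GHz-band sensor sweeping 0.2--0.7 m at 1 mm resolution with a
#' 0.01 s transmission interval.
#'
#' @param center_frequency Carrier frequency in Hz.  The phase-to-distance
#'   conversion uses this value.
#' @param speed_of_light Propagation speed in m/s.
#' @param frame_interval Time between successive sweeps, in seconds.
#' @param range_start,range_stop,range_step Range axis in metres; bins are
#'   placed at `seq(range_start, range_stop, by = range_step)`.
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' length(range_axis(cfg)) # 501 one-millimetre bins over 0.2--0.7 m
#' @export
radar_config <- function(center_frequency = 60.5e9,
                         speed_of_light = 2.998e8,
                         frame_interval = 0.01,
                         range_start = 0.2,
                         range_stop = 0.7,
                         range_step = 0.001) {
  stop_if_not_scalar_pos(center_frequency, "center_frequency")
  stop_if_not_scalar_pos(speed_of_light, "speed_of_light")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(range_step, "range_step")
  if (range_start >= range_stop) {
    stop("`range_start` must be smaller than `range_stop`", call. = FALSE)
  }
  structure(
    list(center_frequency = center_frequency,
         speed_of_light = speed_of_light,
         frame_interval = frame_interval,
         range_start = range_start,
         range_stop = range_stop,
         range_step = range_step),
    class = "radar_config")
}

#' @rdname radar_config
#' @param config A `radar_config`.
#' @export
range_axis <- function(config) {
  seq(config$range_start, config$range_stop, by = config$range_step)
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf("<radar_config> f = %.4g GHz, frame interval %.3g s, range %.3g-%.3g m step %.3g m\n",
              x$center_frequency / 1e9, x$frame_interval,
              x$range_start, x$range_stop, x$range_step))
  invisible(x)
}

#' Radar sweep series
#'
#' A frames-by-bins container of the reflected signal: nonnegative amplitude
#' and wrapped phase (radians in `[0, 2*pi)`) per range bin, with a time axis
#' (seconds) and a range axis (metres).
#'
#' @param amplitude,phase Numeric matrices of identical dimension, one row
#'   per frame, one column per range bin.  Phases must lie in `[0, 2*pi)`.
#' @param time Strictly increasing frame times, seconds.
#' @param range Strictly increasing bin ranges, metres.
#' @return An object of class `sweep_series`.
#' @export
sweep_series <- function(amplitude, phase, time, range) {
  amplitude <- as.matrix(amplitude)
  phase <- as.matrix(phase)
  if (!identical(dim(amplitude), dim(phase))) {
    stop("`amplitude` and `phase` must have the same dimensions", call. = FALSE)
  }
  if (nrow(amplitude) != length(time) || ncol(amplitude) != length(range)) {
    stop("axes do not match the matrix dimensions", call. = FALSE)
  }
  if (length(time) < 1L) stop("a sweep series needs at least one frame", call. = FALSE)
  if (any(diff(time) <= 0) || (length(range) > 1L && any(diff(range) <= 0))) {
    stop("`time` and `range` axes must be strictly increasing", call. = FALSE)
  }
  if (any(amplitude < 0)) stop("amplitudes must be nonnegative", call. = FALSE)
  if (any(phase < 0 | phase >= 2 * pi)) {
    stop("phases must lie in [0, 2*pi)", call. = FALSE)
  }
  structure(list(amplitude = amplitude, phase = phase,
                 time = as.numeric(time), range = as.numeric(range)),
            class = "sweep_series")
}

#' @export
print.sweep_series <- function(x, ...) {
  cat(sprintf("<sweep_series> %d frames x %d range bins, %.4g-%.4g s, %.3g-%.3g m\n",
              nrow(x$amplitude), ncol(x$amplitude),
              min(x$time), max(x$time), min(x$range), max(x$range)))
  invisible(x)
}

#' @export
plot.sweep_series <- function(x, ...) {
  graphics::image(x$time, x$range, x$amplitude,
                  xlab = "time (s)", ylab = "range (m)",
                  main = "sweep amplitude", ...)
  invisible(x)
}

#' Chest-displacement trace
#'
#' A uniformly sampled displacement series in millimetres.  Under the
#' expiration-positive sign convention the value rises while the chest
#' recedes from a front-mounted radar (exhalation) and falls during
#' inhalation.  Only displacement changes are meaningful; the absolute
#' radar-to-chest offset is discarded.
#'
#' @param values Displacement values, mm.
#' @param sampling_interval Sample spacing, seconds.
#' @param start_time Time of the first sample, seconds.
#' @param expiration_positive Logical sign-convention flag.
#' @return An object of class `displacement_trace`.
#' @export
displacement_trace <- function(values, sampling_interval,
                               start_time = 0,
                               expiration_positive = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("`values` must be nonempty and finite", call. = FALSE)
  }
  stop_if_not_scalar_pos(sampling_interval, "sampling_interval")
  structure(list(values = values,
                 sampling_interval = sampling_interval,
                 start_time = start_time,
                 expiration_positive = isTRUE(expiration_positive)),
            class = "displacement_trace")
}

#' @export
length.displacement_trace <- function(x) length(x$values)

#' Sample times of a displacement trace
#' @param trace A `displacement_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1L) * trace$sampling_interval
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("<displacement_trace> %d samples @ %.3g s (%.4g s), range [%.3g, %.3g] mm, %s\n",
              length(x$values), x$sampling_interval,
              length(x$values) * x$sampling_interval,
              min(x$values), max(x$values),
              if (x$expiration_positive) "expiration-positive" else "expiration-negative"))
  invisible(x)
}

#' @export
plot.displacement_trace <- function(x, annotation = NULL, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = "displacement (mm)", ...)
  if (!is.null(annotation)) {
    iv <- annotation$intervals
    cols <- c(resp = NA, hold = grDevices::adjustcolor("steelblue", 0.25),
              swal = grDevices::adjustcolor("firebrick", 0.35))
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(iv))) {
      col <- cols[[iv$label[i]]]
      if (!is.na(col)) {
        graphics::rect(iv$start_s[i], usr[3], iv$end_s[i], usr[4],
                       col = col, border = NA)
      }
    }
    graphics::lines(trace_times(x), x$values)
  }
  invisible(x)
}

#' Activity annotation
#'
#' Labelled ground-truth intervals of a trial: respiring (`"resp"`),
#' commanded breath-hold (`"hold"`) and swallow pause (`"swal"`).  Hold
#' intervals already include the instruction delay (the lag between the
#' on-screen command and the subject's response).
#'
#' @param intervals A data frame with columns `start_s`, `end_s`, `label`.
#' @param instruction_delay_applied Logical provenance flag.
#' @return An object of class `activity_annotation`.
#' @export
activity_annotation <- function(intervals, instruction_delay_applied = TRUE) {
  intervals <- as.data.frame(intervals)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(intervals))) {
    stop("`intervals` needs columns start_s, end_s, label", call. = FALSE)
  }
  intervals$label <- as.character(intervals$label)
  bad <- setdiff(unique(intervals$label), c("resp", "hold", "swal"))
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(intervals$start_s >= intervals$end_s)) {
    stop("interval starts must precede ends", call. = FALSE)
  }
  intervals <- intervals[order(intervals$start_s), , drop = FALSE]
  if (nrow(intervals) > 1L &&
      any(intervals$start_s[-1L] < intervals$end_s[-nrow(intervals)] - 1e-9)) {
    stop("intervals must not overlap", call. = FALSE)
  }
  rownames(intervals) <- NULL
  structure(list(intervals = intervals,
                 instruction_delay_applied = isTRUE(instruction_delay_applied)),
            class = "activity_annotation")
}

#' @export
print.activity_annotation <- function(x, ...) {
  tab <- table(x$intervals$label)
  cat(sprintf("<activity_annotation> %d intervals (%s), %.4g-%.4g s\n",
              nrow(x$intervals),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              min(x$intervals$start_s), max(x$intervals$end_s)))
  invisible(x)
}
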