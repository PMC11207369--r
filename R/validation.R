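# steady-state initial conditions for an IIR filter (the classic
# lfilter_zi construction): the state that makes a unit-step input produce
# a unit-step output from sample one, so forward-backward filtering leaves
# a constant signal exactly unchanged.
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1L]
  a <- c(a, rep(0, n - length(a))) / a[1L]
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

# direct-form II transposed IIR filter with explicit initial state
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1L]
  a <- c(a, rep(0, n - length(a))) / a[1L]
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    for (j in seq_len(n - 2L)) {
      z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
    }
    z[n - 1L] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

#' Zero-phase Butterworth low-pass for the reference channel
#'
#' The band-sensor reference channel is denoised with an order-4 Butterworth
#' low-pass at 5 Hz, applied forward and backward so the result is
#' zero-phase (the effective magnitude response is squared).  Odd-reflection
#' padding plus steady-state filter initialisation remove edge transients,
#' so the DC gain is exactly 1 (a constant signal passes unchanged).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz (must exceed twice the cutoff).
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order (of one pass).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_reference <- function(x, fs = 100, cutoff = 5, order = 4) {
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff", call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- bf$b; a <- bf$a
  padlen <- 3L * max(length(a), length(b))
  if (length(x) <= padlen) {
    stop(sprintf("input too short for filter warm-up (need > %d samples)",
                 padlen), call. = FALSE)
  }
  n <- length(x)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- iir_steady_state(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Waveform similarity between two channels
#'
#' Zero-lag Pearson correlation of the mean-removed segments, in
#' `[-1, 1]`; this is the metric used to score agreement between the
#' radar-derived displacement and the band-sensor reference.  Optionally
#' the maximum over a small range of integer-sample lags can be taken to
#' absorb a fixed sensor delay.
#'
#' @param a,b Equal-length numeric segments (length >= 2), not constant.
#' @param max_lag Maximum lag in samples to search over (0 = zero-lag
#'   only).
#' @return Correlation in `[-1, 1]`, or `NA` if either input is constant.
#' @export
cross_correlation <- function(a, b, max_lag = 0) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("`a` and `b` must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input; correlation indeterminate")
    return(NA_real_)
  }
  if (max_lag == 0) return(stats::cor(a, b))
  n <- length(a)
  max_lag <- min(max_lag, n - 2L)
  best <- -Inf
  for (L in -max_lag:max_lag) {
    ia <- max(1L, 1L - L):min(n, n - L)
    r <- stats::cor(a[ia], b[ia + L])
    if (is.finite(r) && r > best) best <- r
  }
  best
}

#' Extract respire-only evaluation segments
#'
#' Carves fixed-length (default 5 s, enough for one full respiratory cycle)
#' non-overlapping segments out of the annotated respiring intervals of one
#' trial, up to `per_trial` segments.  If less respiring time is available,
#' fewer segments are returned.
#'
#' @param trace A [displacement_trace()].
#' @param annotation An [activity_annotation()].
#' @param segment_s Segment length, seconds.
#' @param per_trial Maximum segments per trial.
#' @return List of segments, each `list(values, start_s)`.
#' @export
segment_respire_intervals <- function(trace, annotation,
                                      segment_s = 5, per_trial = 3) {
  if (!inherits(trace, "displacement_trace")) stop("`trace` must be a displacement_trace", call. = FALSE)
  dt <- trace$sampling_interval
  L <- round(segment_s / dt)
  iv <- annotation$intervals
  iv <- iv[iv$label == "resp", , drop = FALSE]
  out <- list()
  tmax <- trace$start_time + (length(trace$values) - 1L) * dt
  for (i in seq_len(nrow(iv))) {
    s <- iv$start_s[i]
    while (length(out) < per_trial &&
           s + segment_s <= min(iv$end_s[i], tmax) + 1e-9) {
      i0 <- round((s - trace$start_time) / dt) + 1L
      out[[length(out) + 1L]] <- list(values = trace$values[i0:(i0 + L - 1L)],
                                      start_s = s)
      s <- s + segment_s
    }
    if (length(out) >= per_trial) break
  }
  out
}

#' Respiratory pattern before and after a swallow
#'
#' Automates the pre/post-swallow respiratory-phase call: the mean slope of
#' the (expiration-positive) trace over a short span before the pause onset
#' and after its offset.  A clearly positive slope is expiration, clearly
#' negative is inspiration; a slope below the threshold in magnitude -- or
#' missing context at the trace edge -- is indeterminate (no discernible
#' respiratory movement, the "indistinguishable" outcome).
#'
#' @param trace A [displacement_trace()] in the expiration-positive
#'   convention.
#' @param swallow_interval Numeric `c(start_s, end_s)` of the pause.
#' @param span_s Span used on each side, seconds.
#' @param slope_threshold Minimum absolute slope (mm/s) to call a phase;
#'   default is 10\% of the trace's median absolute slope, so the threshold
#'   scales with breathing amplitude.
#' @return An object of class `swallow_pattern_call`: list with `pre` and
#'   `post` in `{"expiration", "inspiration", "indeterminate"}` and the
#'   measured `slopes` (mm/s).
#' @export
respiratory_pattern <- function(trace, swallow_interval, span_s = 0.8,
                                slope_threshold = NULL) {
  if (!inherits(trace, "displacement_trace")) stop("`trace` must be a displacement_trace", call. = FALSE)
  dt <- trace$sampling_interval
  x <- trace$values
  tt <- trace_times(trace)
  if (is.null(slope_threshold)) {
    slope_threshold <- 0.1 * stats::median(abs(diff(x))) / dt
  }
  side_slope <- function(t0, t1) {
    i <- which(tt >= t0 - 1e-9 & tt <= t1 + 1e-9)
    if (length(i) < max(3L, round(span_s / dt) * 0.9)) return(NA_real_)
    stats::cov(tt[i], x[i]) / stats::var(tt[i]) # least-squares slope
  }
  call_side <- function(sl) {
    if (is.na(sl)) "indeterminate"
    else if (sl > slope_threshold) "expiration"
    else if (sl < -slope_threshold) "inspiration"
    else "indeterminate"
  }
  pre_sl <- side_slope(swallow_interval[1] - span_s, swallow_interval[1])
  post_sl <- side_slope(swallow_interval[2], swallow_interval[2] + span_s)
  structure(list(pre = call_side(pre_sl), post = call_side(post_sl),
                 slopes = c(pre = pre_sl, post = post_sl),
                 threshold = slope_threshold),
            class = "swallow_pattern_call")
}

#' @export
print.swallow_pattern_call <- function(x, ...) {
  cat(sprintf("<swallow_pattern_call> %s -> swallow -> %s\n", x$pre, x$post))
  invisible(x)
}

#' Summarise per-segment waveform correlations
#'
#' Pools the segment-level radar/reference correlations: per-subject mean
#' and standard deviation, the pooled mean and standard deviation over all
#' segments, and a correlation histogram (0.05-wide bins over `[-1, 1]`).
#'
#' @param r Numeric vector of per-segment correlations.
#' @param subject Subject identifier per segment.
#' @return An object of class `correlation_summary`.
#' @export
correlation_summary <- function(r, subject) {
  if (length(r) != length(subject)) stop("`r` and `subject` must align", call. = FALSE)
  if (any(!is.na(r) & abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]", call. = FALSE)
  keep <- !is.na(r)
  r <- r[keep]; subject <- as.character(subject)[keep]
  per <- do.call(rbind, lapply(split(r, subject), function(v) {
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  per <- cbind(subject = rownames(per), per)
  rownames(per) <- NULL
  h <- graphics::hist(r, breaks = seq(-1, 1, by = 0.05), plot = FALSE)
  structure(list(per_subject = per,
                 pooled_mean = mean(r), pooled_sd = stats::sd(r),
                 histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                                        upper = h$breaks[-1L],
                                        count = h$counts),
                 n = length(r)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("<correlation_summary> %d segments, pooled r = %.2f (sd %.2f), %d subjects\n",
              x$n, x$pooled_mean, x$pooled_sd, nrow(x$per_subject)))
  invisible(x)
}
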