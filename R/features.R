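#' Movement-range features (10 symmetric inter-quantile spans)
#'
#' Chest-movement range separates respiring (large) from breath-holding
#' (near zero), and trimmed measures like the interquartile range resist
#' noise spikes.  The family generalises that idea: the spans
#' `q(50 + 5k) - q(50 - 5k)` percent for `k = 1..10`, so `k = 5` is the
#' interquartile range and `k = 10` is the full max - min range.  Spans are
#' nonnegative and nondecreasing in `k`.
#'
#' @param x Numeric window values (length >= 2).
#' @return Numeric vector of 10 spans, names `range_01..range_10`.
#' @export
movement_range_features <- function(x) {
  if (length(x) < 2L) stop("window must have at least 2 samples", call. = FALSE)
  k <- 1:10
  hi <- stats::quantile(x, 0.5 + 0.05 * k, names = FALSE, type = 7)
  lo <- stats::quantile(x, 0.5 - 0.05 * k, names = FALSE, type = 7)
  stats::setNames(hi - lo, sprintf("range_%02d", k))
}

#' Autocorrelation features (10 fixed lags)
#'
#' Respiration is quasi-periodic with a cycle of roughly 4 s, so the
#' mean-removed, variance-normalised autocorrelation of a respiring window
#' shows a peak near the cycle length, while holds and swallow pauses break
#' the periodicity.  Values are taken at lags 0.4, 0.8, ..., 4.0 s; a lag at
#' or beyond the window length returns 0 (zero-padding convention), and a
#' zero-variance window returns all zeros.
#'
#' @param x Numeric window values.
#' @param sampling_interval Sample spacing, seconds.
#' @return Numeric vector of 10 correlations in `[-1, 1]`, names
#'   `ac_01..ac_10`.
#' @export
autocorrelation_features <- function(x, sampling_interval = 0.01) {
  n <- length(x)
  lags <- round(0.4 * (1:10) / sampling_interval)
  if (n < 2L) stop("window too short", call. = FALSE)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  out <- numeric(10)
  if (denom > 0) {
    for (i in seq_along(lags)) {
      L <- lags[i]
      if (L < n) {
        out[i] <- sum(xc[1:(n - L)] * xc[(1 + L):n]) / denom
      }
    }
  }
  stats::setNames(out, sprintf("ac_%02d", 1:10))
}

#' FFT features (10 lowest positive-frequency magnitudes)
#'
#' High frequencies carry no respiratory information, so only the low end
#' of the spectrum is kept: the magnitudes of the 10 lowest
#' positive-frequency DFT bins of the mean-subtracted window (0.25--2.5 Hz
#' for a 4 s window at 100 Hz).  Subtracting the mean removes the DC
#' component.
#'
#' @param x Numeric window values (length >= 20).
#' @return Numeric vector of 10 nonnegative magnitudes, names
#'   `fft_01..fft_10`.
#' @export
fft_features <- function(x) {
  if (length(x) < 20L) stop("window must have at least 20 samples", call. = FALSE)
  sp <- Mod(stats::fft(x - mean(x)))
  stats::setNames(sp[2:11], sprintf("fft_%02d", 1:10))
}

#' Histogram features (10 equal-width bins)
#'
#' Captures the overall waveform shape: the window's value range
#' (min to max) is divided into ten equal bins and the fraction of samples
#' per bin reported (fractions, so the feature is window-length
#' independent).  A respiring window's raised-cosine dwell at the
#' turning points gives the characteristic two-peak (U) shape; a hold
#' window concentrates its mass.  The maximum sample falls in the last bin
#' (right-closed top bin); a flat window puts all mass in the first bin by
#' convention, preserving the hold-versus-respire contrast.
#'
#' @param x Numeric window values.
#' @return Numeric vector of 10 fractions summing to 1, names
#'   `hist_01..hist_10`.
#' @export
histogram_features <- function(x) {
  if (length(x) < 1L) stop("window must be nonempty", call. = FALSE)
  mn <- min(x); mx <- max(x)
  out <- numeric(10)
  if (mx > mn) {
    idx <- pmin(floor((x - mn) / (mx - mn) * 10) + 1L, 10L)
    out <- tabulate(idx, nbins = 10L) / length(x)
  } else {
    out[1L] <- 1
  }
  stats::setNames(out, sprintf("hist_%02d", 1:10))
}

#' The 40-dimensional designed feature vector
#'
#' Concatenates the four designed families in fixed order -- movement range,
#' autocorrelation, FFT, histogram, 10 values each -- giving the
#' 40-dimensional input used for training.
#'
#' @inheritParams autocorrelation_features
#' @return Named numeric vector of length 40.
#' @examples
#' length(designed_features(sin(2 * pi * (0:399) / 400)))
#' @export
designed_features <- function(x, sampling_interval = 0.01) {
  c(movement_range_features(x),
    autocorrelation_features(x, sampling_interval),
    fft_features(x),
    histogram_features(x))
}

#' Designed feature table for a window dataset
#'
#' @param dataset A [build_dataset()] result.
#' @return A data frame: `subject`, `start_s`, `label`, then the 40 designed
#'   feature columns.
#' @export
designed_feature_table <- function(dataset) {
  if (!inherits(dataset, "window_dataset")) {
    stop("`dataset` must be a window_dataset", call. = FALSE)
  }
  feats <- t(apply(dataset$values, 1L, designed_features,
                   sampling_interval = dataset$sampling_interval))
  cbind(dataset$meta, as.data.frame(feats))
}

#' General time-series features
#'
#' A broad catalogue of standard time-series summary statistics (location,
#' spread, moments, energy, change statistics, crossings and runs,
#' quantiles, autocorrelations, spectral summaries, complexity), mirroring
#' the kind of exhaustive feature sets produced by generic extraction
#' libraries.  The catalogue length is recorded, not contractual.  Use
#' [drop_constant_features()] to remove zero-variance (and duplicated)
#' columns at the dataset level before training.
#'
#' @inheritParams autocorrelation_features
#' @return A named numeric vector of finite features.
#' @export
general_features <- function(x, sampling_interval = 0.01) {
  n <- length(x)
  if (n < 20L) stop("window must have at least 20 samples", call. = FALSE)
  xc <- x - mean(x)
  s <- stats::sd(x)
  dx <- diff(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  above <- x > mean(x)
  runs <- rle(above)
  sp <- Mod(stats::fft(xc))[2:(n %/% 2 + 1L)]
  psum <- sum(sp^2)
  pfrac <- if (psum > 0) sp^2 / psum else rep(0, length(sp))
  freqs <- (seq_along(sp)) / (n * sampling_interval)
  qs <- stats::quantile(x, c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95),
                        names = FALSE, type = 7)
  acf10 <- autocorrelation_features(x, sampling_interval)
  feats <- c(
    mean = mean(x), median = stats::median(x), sd = s, var = s^2,
    min = min(x), max = max(x), range = max(x) - min(x),
    abs_energy = sum(x^2), rms = sqrt(mean(x^2)),
    mean_abs = mean(abs(x)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    sum = sum(x),
    q05 = qs[1], q10 = qs[2], q25 = qs[3], q50 = qs[4],
    q75 = qs[5], q90 = qs[6], q95 = qs[7],
    iqr = qs[5] - qs[3],
    mean_change = mean(dx), mean_abs_change = mean(abs(dx)),
    max_abs_change = max(abs(dx)), sd_change = stats::sd(dx),
    abs_sum_change = sum(abs(dx)),
    mean_second_diff = mean(diff(dx)),
    n_above_mean = sum(above), n_below_mean = sum(!above),
    longest_run_above = if (any(runs$values)) max(runs$lengths[runs$values]) else 0,
    longest_run_below = if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0,
    zero_crossings = sum(diff(sign(xc + (xc == 0) * 1e-12)) != 0),
    first_location_max = which.max(x) / n,
    first_location_min = which.min(x) / n,
    count_above_q90 = sum(x > qs[6]), count_below_q10 = sum(x < qs[2]),
    spectral_centroid = if (psum > 0) sum(freqs * pfrac) else 0,
    spectral_entropy = if (psum > 0) -sum(pfrac[pfrac > 0] *
                                            log(pfrac[pfrac > 0])) else 0,
    spectral_peak_freq = if (psum > 0) freqs[which.max(sp)] else 0,
    spectral_peak_mag = if (length(sp)) max(sp) else 0,
    low_band_power = sum(pfrac[freqs <= 0.5]),
    mid_band_power = sum(pfrac[freqs > 0.5 & freqs <= 2]),
    cid_ce = sqrt(sum(dx^2)),
    mean_crossings_rate = sum(diff(above) != 0) / n,
    acf10)
  feats[!is.finite(feats)] <- 0
  feats
}

#' Drop constant and duplicated feature columns
#'
#' Dataset-level cleanup for the general feature arm: removes columns with
#' zero variance and exact duplicates of earlier columns, which carry no
#' information and can hurt training.
#'
#' @param x Numeric feature matrix (rows = windows).
#' @return The matrix with offending columns removed; attribute
#'   `n_dropped` records how many went.
#' @export
drop_constant_features <- function(x) {
  x <- as.matrix(x)
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  x2 <- x[, keep, drop = FALSE]
  dup <- duplicated(t(x2))
  out <- x2[, !dup, drop = FALSE]
  attr(out, "n_dropped") <- ncol(x) - ncol(out)
  out
}

#' Estimate the respiratory cycle from a trace
#'
#' The subject's respiratory period is read off the autocorrelation of the
#' displacement trace: the lag of the highest autocorrelation peak in the
#' physiological search band (1.5--8 s by default).  If no peak in the band
#' reaches `min_peak`, the period is indeterminate (`NA`), as for a
#' non-periodic signal.
#'
#' @param trace A [displacement_trace()] (at least 10 s of respiring).
#' @param band Search band for the period, seconds.
#' @param min_peak Minimum autocorrelation a peak must reach.
#' @return Estimated period in seconds, or `NA` if indeterminate.
#' @export
estimate_respiratory_cycle <- function(trace, band = c(1.5, 8),
                                       min_peak = 0.3) {
  if (!inherits(trace, "displacement_trace")) {
    stop("`trace` must be a displacement_trace", call. = FALSE)
  }
  dt <- trace$sampling_interval
  x <- trace$values
  n <- length(x)
  if (n * dt < 10) stop("need at least 10 s of trace", call. = FALSE)
  max_lag <- min(n - 1L, ceiling(band[2] / dt))
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(NA_real_)
  r <- vapply(seq_len(max_lag), function(L) {
    sum(xc[1:(n - L)] * xc[(1 + L):n]) / denom
  }, numeric(1))
  lags_s <- seq_len(max_lag) * dt
  in_band <- lags_s >= band[1] & lags_s <= band[2]
  # local maxima of r within the band
  peaks <- which(in_band &
                   c(FALSE, diff(r) > 0) &
                   c(diff(r) < 0, FALSE) &
                   r >= min_peak)
  if (!length(peaks)) return(NA_real_)
  lags_s[peaks[which.max(r[peaks])]]
}
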