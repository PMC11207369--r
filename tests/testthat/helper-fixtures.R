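# shared fixture builders (all data built in code at test time)

# sinusoidal displacement trace: amplitude mm, period s
sine_trace <- function(duration_s = 30, period_s = 4, amplitude = 3,
                       dt = 0.01, noise_sd = 0, seed = NULL) {
  n <- round(duration_s / dt)
  x <- amplitude * sin(2 * pi * (seq_len(n) - 1) * dt / period_s)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  displacement_trace(x, dt)
}

# noiseless subject profile (quasi-periodic jitter kept unless disabled)
quiet_profile <- function(seed, ...) {
  subject_profile(motion_noise_sd = 0, phase_noise_sd = 0, seed = seed, ...)
}

# a sweep series with a fixed amplitude peak per frame and given phases
toy_sweeps <- function(peak_bins, phases = NULL, n_bins = 20, dt = 0.01) {
  n <- length(peak_bins)
  amp <- matrix(0.1, n, n_bins)
  amp[cbind(seq_len(n), peak_bins)] <- 1
  if (is.null(phases)) phases <- rep(0, n)
  ph <- matrix(phases, n, n_bins)
  sweep_series(amp, ph, time = (seq_len(n) - 1) * dt,
               range = 0.2 + (seq_len(n_bins) - 1) * 0.001)
}

# three well-separated Gaussian blobs for classifier sanity checks
blob_data <- function(n_per_class = 30, sep = 10, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  x <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per_class, centers[k, 1], sd),
          rnorm(n_per_class, centers[k, 2], sd))
  }))
  colnames(x) <- c("f1", "f2")
  list(x = as.data.frame(x),
       y = factor(rep(c("a", "b", "c"), each = n_per_class)),
       groups = rep_len(paste0("g", 1:4), 3 * n_per_class))
}
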