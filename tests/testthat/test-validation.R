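test_that("the zero-phase Butterworth has unit DC gain and a sharp cutoff", {
  # constant passes exactly
  expect_lt(max(abs(lowpass_reference(rep(3, 300), fs = 100) - 3)), 1e-9)
  # 1 Hz sine amplitude preserved within 1% (measured away from the edges)
  t <- (0:1999) * 0.01
  y1 <- lowpass_reference(sin(2 * pi * 1 * t), fs = 100)
  mid <- 500:1500
  expect_equal(max(abs(y1[mid])), 1, tolerance = 0.01)
  # 20 Hz sine attenuated by at least 40 dB
  y20 <- lowpass_reference(sin(2 * pi * 20 * t), fs = 100)
  expect_lt(max(abs(y20[mid])), 0.01)
  expect_error(lowpass_reference(rnorm(10), fs = 100), "too short")
  expect_error(lowpass_reference(rnorm(100), fs = 8), "twice the cutoff")
})

test_that("cross-correlation is a bounded, symmetric, scale-invariant similarity", {
  set.seed(51)
  x <- rnorm(300); y <- rnorm(300)
  expect_equal(cross_correlation(x, x), 1)
  expect_equal(cross_correlation(x, -x), -1)
  expect_equal(cross_correlation(x, y), cross_correlation(y, x))
  expect_equal(cross_correlation(x, 2 * y + 3), cross_correlation(x, y))
  expect_warning(r <- cross_correlation(x, rep(1, 300)), "constant")
  expect_true(is.na(r))
  # independent white noise: |r| < 0.15 in at least 95% of trials
  hits <- sum(replicate(200, abs(cross_correlation(rnorm(500),
                                                   rnorm(500))) < 0.15))
  expect_gte(hits / 200, 0.95)
  # the lag-search variant absorbs a small shift
  s <- sin(2 * pi * (0:499) / 100)
  shifted <- c(rep(0, 10), s[1:490])
  expect_gt(cross_correlation(s, shifted, max_lag = 50),
            cross_correlation(s, shifted))
})

test_that("respire segments are carved 5 s at a time, capped per trial", {
  ann <- activity_annotation(data.frame(start_s = 0, end_s = 30,
                                        label = "resp"))
  segs <- segment_respire_intervals(sine_trace(30), ann)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) length(s$values), 0L) == 500))
  # less than 5 s of respiring -> nothing
  ann2 <- activity_annotation(data.frame(start_s = c(0, 4), end_s = c(4, 8),
                                         label = c("resp", "hold")))
  expect_length(segment_respire_intervals(sine_trace(8), ann2), 0)
})

test_that("a cohort's segment count is subjects x trials x 3", {
  rec <- simulate_cohort(20, 10, seed = 61, measure = "truth")
  n_segs <- sum(vapply(rec, function(r) {
    length(segment_respire_intervals(r$trace, r$annotation))
  }, 0L))
  expect_equal(n_segs, 600)
})

test_that("radar-derived and band channels correlate strongly on clean simulation", {
  cfg <- radar_config()
  rs <- c()
  for (seed in 71:73) {
    p <- subject_profile(seed = seed, motion_noise_sd = 0)
    sim <- simulate_trial(p, config = cfg, measure = "radar", seed = seed)
    snr_sd <- sd(sim$truth$values) / sqrt(10)
    band <- render_band_signal(sim$truth, noise_sd = snr_sd, seed = seed)
    band <- lowpass_reference(band, fs = 1 / cfg$frame_interval)
    for (seg in segment_respire_intervals(sim$trace, sim$annotation)) {
      i0 <- round(seg$start_s / cfg$frame_interval) + 1
      rs <- c(rs, cross_correlation(seg$values,
                                    band[i0:(i0 + length(seg$values) - 1)]))
    }
  }
  summ <- correlation_summary(rs, rep("s", length(rs)))
  expect_gt(summ$pooled_mean, 0.9)
  expect_equal(summ$n, length(rs))
  expect_equal(sum(summ$histogram$count), length(rs))
})

test_that("pattern calls read the slope around the pause and flip with the sign", {
  p <- subject_profile(seed = 81, motion_noise_sd = 0)
  m <- generate_motion(p, default_schedule(p))
  sw <- m$annotation$intervals[m$annotation$intervals$label == "swal", ]
  call <- respiratory_pattern(m$trace, c(sw$start_s, sw$end_s))
  # mid-expiration swallow: expiration on both sides
  expect_equal(call$pre, "expiration")
  expect_equal(call$post, "expiration")
  flipped <- displacement_trace(-m$trace$values, m$trace$sampling_interval)
  call2 <- respiratory_pattern(flipped, c(sw$start_s, sw$end_s))
  expect_equal(call2$pre, "inspiration")
  expect_equal(call2$post, "inspiration")
  # flat context below threshold is indeterminate
  set.seed(9)
  flat <- displacement_trace(rnorm(1000, 0, 0.01), 0.01)
  call3 <- respiratory_pattern(flat, c(4, 5), slope_threshold = 1)
  expect_equal(call3$pre, "indeterminate")
  expect_equal(call3$post, "indeterminate")
  # missing context at the trace edge is indeterminate
  call4 <- respiratory_pattern(m$trace, c(0.1, 0.4))
  expect_equal(call4$pre, "indeterminate")
})

test_that("expiration-phase swallows are dominated by expiration-expiration calls", {
  rec <- simulate_cohort(10, 2, seed = 91, measure = "truth")
  patt <- table(unlist(lapply(rec, function(r) {
    sw <- r$annotation$intervals[r$annotation$intervals$label == "swal", ]
    call <- respiratory_pattern(r$trace, c(sw$start_s[1], sw$end_s[1]))
    paste(call$pre, call$post, sep = "->")
  })))
  expect_equal(names(patt)[which.max(patt)], "expiration->expiration")
  expect_gt(max(patt) / sum(patt), 0.5)
})
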