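test_that("range-bin selection takes the mode of per-frame argmaxes with low-bin ties", {
  expect_equal(select_range_bin(toy_sweeps(rep(8, 10))), 8)
  expect_equal(select_range_bin(toy_sweeps(c(15, 15, 16, 15))), 15)
  # two bins each modal in half the frames -> smaller index
  expect_equal(select_range_bin(toy_sweeps(c(5, 9, 9, 5))), 5)
  # argmax tie within a frame -> lowest bin
  amp <- matrix(0.1, 3, 6); amp[, 3] <- 1; amp[, 5] <- 1
  sw <- sweep_series(amp, matrix(0, 3, 6), time = (0:2) * 0.01,
                     range = 0.2 + (0:5) * 0.001)
  expect_equal(select_range_bin(sw), 3)
})

test_that("phase extraction returns the recorded phases at one bin", {
  ph <- c(0.3, 1.2, 6.1)
  sw <- toy_sweeps(rep(4, 3), phases = ph)
  expect_identical(extract_phase(sw, 4), ph)
  expect_length(extract_phase(toy_sweeps(1, phases = 0.5), 1), 1)
  expect_error(extract_phase(sw, 21), "out of range")
  expect_error(sweep_series(matrix(1, 2, 2), matrix(7, 2, 2),
                            (0:1) * 0.01, c(0.2, 0.201)), "0, 2\\*pi")
})

test_that("unwrapping corrects jumps strictly exceeding pi", {
  expect_equal(unwrap_phase(c(0.10, 6.20)), c(0.10, 6.20 - 2 * pi))
  expect_equal(unwrap_phase(rep(1.5, 10)), rep(1.5, 10))
  # linear ramp 0 -> 4*pi wrapped then recovered
  ramp <- seq(0, 4 * pi, length.out = 100)
  expect_equal(unwrap_phase(ramp %% (2 * pi)), ramp, tolerance = 1e-12)
  # an exactly-pi difference is left alone (strict inequality)
  expect_equal(unwrap_phase(c(0, pi)), c(0, pi))
})

test_that("unwrapping matches the principal-increment oracle on random ramps", {
  set.seed(101)
  for (i in 1:1000) {
    inc <- runif(60, -pi + 1e-6, pi - 1e-6)
    true <- runif(1, 0, 2 * pi) + cumsum(c(0, inc))
    wrapped <- true %% (2 * pi)
    # oracle: cumulative sum of principal-value increments
    oracle <- wrapped[1] +
      cumsum(c(0, Arg(exp(1i * diff(wrapped)))))
    got <- unwrap_phase(wrapped)
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_equal(got, true, tolerance = 1e-9)
    expect_true(all(abs(diff(got)) <= pi + 1e-12))
    expect_true(all(abs((got - wrapped) / (2 * pi) -
                          round((got - wrapped) / (2 * pi))) < 1e-9))
  }
})

test_that("phase-to-distance conversion matches the radar sensitivity relation", {
  cfg60 <- radar_config(center_frequency = 60e9)
  # 144 degrees at 60 GHz is about 1 mm
  expect_equal(phase_to_displacement(deg <- 144 * pi / 180, cfg60) * 1000,
               1.00, tolerance = 0.005)
  expect_equal(phase_to_displacement(0, cfg60), 0)
  # 6.1 degrees at 60.5 GHz is about 42 micrometres
  expect_equal(phase_to_displacement(6.1 * pi / 180, radar_config()) * 1e6,
               42, tolerance = 0.5 / 42)
  # linear and sign-preserving; doubling f halves the distance
  cfg121 <- radar_config(center_frequency = 121e9)
  x <- c(-2, -0.5, 0.3, 1.7)
  expect_equal(phase_to_displacement(2 * x, cfg60),
               2 * phase_to_displacement(x, cfg60))
  expect_equal(phase_to_displacement(x, cfg121),
               phase_to_displacement(x, radar_config(center_frequency = 60.5e9)) *
                 60.5 / 121)
  expect_equal(displacement_to_phase(phase_to_displacement(x, cfg60), cfg60), x)
})

test_that("constant-phase sweeps estimate an all-zero trace", {
  sw <- toy_sweeps(rep(6, 30), phases = rep(2.2, 30))
  est <- estimate_displacement(sw)
  expect_equal(est$values, rep(0, 30))
})

test_that("noiseless rendered sweeps round-trip through the estimator", {
  cfg <- radar_config()
  p <- subject_profile(seed = 21, motion_noise_sd = 0, phase_noise_sd = 0)
  m <- generate_motion(p, trial_schedule("resp", 12))
  sw <- render_sweeps(m$trace, cfg, baseline_distance = p$baseline_distance,
                      phase_noise_sd = 0, amplitude_noise_sd = 0)
  est <- estimate_displacement(sw, cfg)
  err <- est$values - m$trace$values
  expect_gt(cor(est$values, m$trace$values), 0.999)
  expect_lt(max(abs(err - mean(err))), 0.1)
})

test_that("with 6.1 degree phase noise recovery still correlates above 0.98", {
  cfg <- radar_config()
  for (seed in c(31, 32, 33)) {
    p <- subject_profile(seed = seed, motion_noise_sd = 0)
    m <- generate_motion(p, trial_schedule("resp", 12))
    sw <- render_sweeps(m$trace, cfg, profile = p, seed = seed)
    est <- estimate_displacement(sw, cfg)
    expect_gt(cor(est$values, m$trace$values), 0.98)
  }
})

test_that("per-frame motion beyond a quarter wavelength aliases; below it recovers", {
  cfg <- radar_config()
  lambda4_mm <- cfg$speed_of_light / (4 * cfg$center_frequency) * 1000
  run_ramp <- function(step_mm) {
    tr <- displacement_trace(step_mm * (0:19), 0.01)
    sw <- render_sweeps(tr, cfg, baseline_distance = 0.3,
                        phase_noise_sd = 0, amplitude_noise_sd = 0)
    diff(estimate_displacement(sw, cfg)$values)
  }
  # 1.2 mm/frame: below the ~1.24 mm boundary, recovered exactly
  expect_equal(run_ramp(1.2), rep(1.2, 19), tolerance = 1e-9)
  # 1.3 mm/frame: wraps -- the recovered increment is the true step minus
  # half a wavelength (the documented failure mode)
  expect_equal(run_ramp(1.3), rep(1.3 - 2 * lambda4_mm, 19), tolerance = 1e-9)
})

test_that("round-trip holds across random profiles in the stated ranges", {
  cfg <- radar_config()
  for (seed in 41:50) {
    p <- subject_profile(seed = seed, motion_noise_sd = 0, phase_noise_sd = 0)
    m <- generate_motion(p, trial_schedule("resp", 10))
    sw <- render_sweeps(m$trace, cfg, baseline_distance = p$baseline_distance,
                        phase_noise_sd = 0, amplitude_noise_sd = 0)
    est <- estimate_displacement(sw, cfg)
    expect_gt(cor(est$values, m$trace$values), 0.999)
  }
})
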