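#' Subject profile for the breathing simulator
#'
#' Collects per-subject physiology: respiratory period (healthy adults span
#' roughly 2.5--5 s), breathing amplitude (anterior-posterior chest motion is
#' under 10 mm), cycle asymmetry, the duration of the deglutition-apnea
#' plateau, radar standoff, and the two noise floors (chest motion jitter and
#' radar phase noise, whose documented standard deviation for this class of
#' sensor is 6.1 degrees).  Arguments left `NULL` are sampled uniformly from
#' the stated physiological range using `seed`.
#'
#' @param breathing_period Respiratory cycle length in seconds, in `[2.5, 5]`.
#' @param breathing_amplitude Peak-to-peak chest displacement in mm, in `[2, 8]`.
#' @param inspiration_fraction Fraction of the cycle spent inhaling, in (0, 1).
#' @param swallow_pause_duration Deglutition-apnea duration in seconds, in
#'   `[0.3, 1.5]`.
#' @param baseline_distance Radar-to-chest standoff in metres, in `[0.25, 0.65]`.
#' @param motion_noise_sd Gaussian jitter added to the chest trajectory, mm.
#' @param period_jitter Breath-to-breath coefficient of variation of the
#'   instantaneous cycle length (0 = strictly periodic).  Resting breathing
#'   in healthy adults varies by roughly 10\% cycle to cycle, which is what
#'   makes the signal quasi-periodic rather than periodic.
#' @param amplitude_jitter Breath-to-breath coefficient of variation of the
#'   breathing amplitude.
#' @param phase_noise_sd Radar phase noise standard deviation, degrees.
#' @param body_movement_sd Scale of an optional slow random-walk posture
#'   drift (mm per sqrt(second)); 0 disables it.
#' @param swallow_cycle_phase Position within the breathing cycle (in cycle
#'   units, expiration occupying `[0, 1 - inspiration_fraction)`) at which a
#'   swallow pause is inserted.  The default 0.35 places it in mid-to-late
#'   expiration, reproducing the dominant
#'   exhalation--swallow--exhalation pattern of healthy adults.
#' @param seed Integer seed used to sample unset fields (and carried along
#'   for downstream noise generation).
#' @return An object of class `subject_profile`.
#' @examples
#' p <- subject_profile(seed = 1)
#' p$breathing_period
#' @export
subject_profile <- function(breathing_period = NULL,
                            breathing_amplitude = NULL,
                            inspiration_fraction = NULL,
                            swallow_pause_duration = NULL,
                            baseline_distance = NULL,
                            motion_noise_sd = 0.05,
                            period_jitter = 0.10,
                            amplitude_jitter = 0.10,
                            phase_noise_sd = 6.1,
                            body_movement_sd = 0,
                            swallow_cycle_phase = 0.35,
                            seed = NULL) {
  draw <- with_seed(seed, list(
    period = stats::runif(1, 2.5, 5.0),
    amplitude = stats::runif(1, 2, 8),
    insp = stats::runif(1, 0.35, 0.45),
    pause = stats::runif(1, 0.3, 1.5),
    baseline = stats::runif(1, 0.30, 0.60)))
  p <- list(
    breathing_period = breathing_period %||% draw$period,
    breathing_amplitude = breathing_amplitude %||% draw$amplitude,
    inspiration_fraction = inspiration_fraction %||% draw$insp,
    swallow_pause_duration = swallow_pause_duration %||% draw$pause,
    baseline_distance = baseline_distance %||% draw$baseline,
    motion_noise_sd = motion_noise_sd,
    period_jitter = period_jitter,
    amplitude_jitter = amplitude_jitter,
    phase_noise_sd = phase_noise_sd,
    body_movement_sd = body_movement_sd,
    swallow_cycle_phase = swallow_cycle_phase,
    seed = seed)
  if (p$breathing_period < 2.5 || p$breathing_period > 5.0) {
    stop("`breathing_period` must lie in [2.5, 5] s", call. = FALSE)
  }
  if (p$breathing_amplitude <= 0 || p$breathing_amplitude >= 10) {
    stop("`breathing_amplitude` must be positive and below 10 mm", call. = FALSE)
  }
  if (p$inspiration_fraction <= 0 || p$inspiration_fraction >= 1) {
    stop("`inspiration_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (p$swallow_pause_duration <= 0) {
    stop("`swallow_pause_duration` must be positive", call. = FALSE)
  }
  if (p$baseline_distance < 0.25 || p$baseline_distance > 0.65) {
    stop("`baseline_distance` must lie in [0.25, 0.65] m", call. = FALSE)
  }
  if (p$motion_noise_sd < 0 || p$phase_noise_sd < 0 || p$body_movement_sd < 0 ||
      p$period_jitter < 0 || p$amplitude_jitter < 0) {
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  }
  if (p$swallow_cycle_phase < 0 || p$swallow_cycle_phase >= 1) {
    stop("`swallow_cycle_phase` must lie in [0, 1)", call. = FALSE)
  }
  structure(p, class = "subject_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> T = %.2f s, A = %.2f mm, insp %.2f, pause %.2f s, standoff %.2f m\n",
              x$breathing_period, x$breathing_amplitude,
              x$inspiration_fraction, x$swallow_pause_duration,
              x$baseline_distance))
  invisible(x)
}

#' Trial schedule
#'
#' An ordered list of commanded activities making up one trial.  Swallow
#' segments are the deglutition-apnea plateau itself and must not exceed
#' 2 s; the schedule must span at least one analysis window (4 s).
#'
#' @param activities Character vector over `"resp"`, `"hold"`, `"swal"`.
#' @param durations Segment durations, seconds.
#' @param instruction_delay Lag (s) between the on-screen command and the
#'   subject's response; applied to breath-hold segments.
#' @return An object of class `trial_schedule`.
#' @examples
#' trial_schedule(c("resp", "hold", "resp"), c(8, 5, 8))
#' @export
trial_schedule <- function(activities, durations, instruction_delay = 0.5) {
  activities <- as.character(activities)
  if (length(activities) == 0L || length(activities) != length(durations)) {
    stop("`activities` and `durations` must be nonempty and equal length",
         call. = FALSE)
  }
  bad <- setdiff(unique(activities), c("resp", "hold", "swal"))
  if (length(bad)) stop("unknown activities: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  if (any(durations[activities == "swal"] > 2)) {
    stop("swallow segments must not exceed 2 s", call. = FALSE)
  }
  if (instruction_delay < 0) stop("`instruction_delay` must be >= 0", call. = FALSE)
  if (sum(durations) < 4) {
    stop("schedule must span at least one 4 s window", call. = FALSE)
  }
  structure(list(activities = activities, durations = as.numeric(durations),
                 instruction_delay = instruction_delay),
            class = "trial_schedule")
}

#' @rdname trial_schedule
#' @param profile A [subject_profile()]; its `swallow_pause_duration` sets the
#'   swallow segment length.
#' @details `default_schedule()` mirrors the commanded trial flow used for
#'   data collection: free breathing, a 5 s commanded breath-hold, recovery
#'   breathing, one water swallow, and trailing breathing.
#' @export
default_schedule <- function(profile) {
  trial_schedule(c("resp", "hold", "resp", "swal", "resp"),
                 c(12, 5, 10, profile$swallow_pause_duration, 10))
}

# raised-cosine breathing cycle, expiration-positive displacement (mm):
# rises -A/2 -> +A/2 over the expiration limb u in [0, 1 - fi), falls back
# over the inspiration limb.  Zero derivative at both turning points gives
# the short end-expiration/end-inspiration dwells seen in real traces (and
# the two-peak window histogram).
cycle_wave <- function(u, amplitude, inspiration_fraction) {
  fe <- 1 - inspiration_fraction
  u <- u %% 1
  out <- numeric(length(u))
  e <- u < fe
  out[e] <- -amplitude / 2 * cos(pi * u[e] / fe)
  out[!e] <- amplitude / 2 * cos(pi * (u[!e] - fe) / inspiration_fraction)
  out
}

#' Generate a ground-truth chest-motion trace
#'
#' Synthesises the chest displacement of one trial.  Respiring segments
#' advance a raised-cosine breathing cycle at the subject's period; hold and
#' swallow segments freeze the cycle, producing a plateau continuous with
#' the adjacent breathing.  The cycle is quasi-periodic: instantaneous
#' period and amplitude are modulated breath to breath by smooth AR(1)
#' processes with correlation time of one cycle and the profile's jitter
#' coefficients of variation (the modulation only evolves while breathing,
#' so plateaus stay flat).  Breath-holds start `instruction_delay` seconds
#' after the command (the annotation records the shifted interval); swallow
#' pauses wait until the realised cycle phase reaches the profile's
#' `swallow_cycle_phase` before freezing, so the pause lands at a
#' physiologically plausible point of the expiration limb.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [trial_schedule()].
#' @param sampling_interval Sample spacing of the output trace, seconds.
#' @param seed Seed for the noise; defaults to the profile's seed.
#' @return A list with elements `trace` (a [displacement_trace()],
#'   expiration-positive) and `annotation` (an [activity_annotation()] of the
#'   true intervals).
#' @examples
#' p <- subject_profile(seed = 3, motion_noise_sd = 0)
#' m <- generate_motion(p, default_schedule(p))
#' plot(m$trace, m$annotation)
#' @export
generate_motion <- function(profile, schedule,
                            sampling_interval = 0.01,
                            seed = profile$seed) {
  if (!inherits(profile, "subject_profile")) stop("`profile` must be a subject_profile", call. = FALSE)
  if (!inherits(schedule, "trial_schedule")) stop("`schedule` must be a trial_schedule", call. = FALSE)
  if (sum(schedule$durations) < 4) {
    stop("schedule shorter than one 4 s window", call. = FALSE)
  }
  dt <- sampling_interval
  T <- profile$breathing_period
  base_rate <- 1 / T
  phi <- exp(-dt / T) # AR(1) coefficient: correlation time = one cycle

  with_seed(seed, {
    # mutable generator state
    u <- stats::runif(1)             # cycle phase of the next frame, cycles
    etaT <- stats::rnorm(1, 0, profile$period_jitter)
    etaA <- stats::rnorm(1, 0, profile$amplitude_jitter)
    uu <- list(); aa <- list()       # per-stretch phase / amplitude factors
    n_done <- 0L
    ann_start <- ann_end <- numeric(0); ann_label <- character(0)
    add_ann <- function(nf, lab) {
      ann_start <<- c(ann_start, n_done * dt)
      ann_end <<- c(ann_end, (n_done + nf) * dt)
      ann_label <<- c(ann_label, lab)
      n_done <<- n_done + nf
    }
    push <- function(us, as_) {
      uu[[length(uu) + 1L]] <<- us
      aa[[length(aa) + 1L]] <<- as_
    }
    ar1_path <- function(state, n, cv) {
      if (cv <= 0) return(list(path = rep(0, n), state = 0))
      innov <- stats::rnorm(n, 0, cv * sqrt(1 - phi^2))
      path <- as.numeric(stats::filter(innov, phi, "recursive",
                                       init = state))
      list(path = path, state = path[n])
    }
    breathe <- function(n_frames, label = "resp") {
      if (n_frames < 1L) return(invisible())
      pT <- ar1_path(etaT, n_frames, profile$period_jitter)
      pA <- ar1_path(etaA, n_frames, profile$amplitude_jitter)
      etaT <<- pT$state; etaA <<- pA$state
      rate <- base_rate / pmax(1 + pT$path, 0.2)
      us <- u + c(0, cumsum(rate[-n_frames] * dt))
      u <<- us[n_frames] + rate[n_frames] * dt
      push(us, 1 + pA$path)
      add_ann(n_frames, label)
    }
    freeze <- function(n_frames, label) {
      if (n_frames < 1L) return(invisible())
      push(rep(u, n_frames), rep(1 + etaA, n_frames))
      add_ann(n_frames, label)
    }
    for (i in seq_along(schedule$activities)) {
      act <- schedule$activities[i]
      nf <- round(schedule$durations[i] / dt)
      if (act == "resp") {
        breathe(nf)
      } else if (act == "hold") {
        breathe(round(schedule$instruction_delay / dt))
        freeze(nf, "hold")
      } else { # swal: breathe on until the realised phase hits the target
        target <- profile$swallow_cycle_phase
        wait <- 0L
        max_wait <- 2L * round(T / dt)
        while (wait < max_wait &&
               ((target - u) %% 1) > base_rate * dt * 1.5) {
          breathe(1L)
          wait <- wait + 1L
        }
        freeze(nf, "swal")
      }
    }
    uu <- unlist(uu); amp_factor <- unlist(aa)
    n <- length(uu)
    clean <- amp_factor * cycle_wave(uu, profile$breathing_amplitude,
                                     profile$inspiration_fraction)
    noise <- stats::rnorm(n, 0, profile$motion_noise_sd)
    if (profile$body_movement_sd > 0) {
      noise <- noise + cumsum(stats::rnorm(n, 0, profile$body_movement_sd *
                                             sqrt(dt)))
    }
  })

  # merge consecutive same-label intervals (delay/wait stubs rejoin resp)
  ann <- data.frame(start_s = ann_start, end_s = ann_end, label = ann_label)
  keep <- c(TRUE, ann$label[-1L] != ann$label[-nrow(ann)])
  grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
  ann <- data.frame(start_s = as.numeric(tapply(ann$start_s, grp, min)),
                    end_s = as.numeric(tapply(ann$end_s, grp, max)),
                    label = ann$label[keep])

  list(trace = displacement_trace(clean + noise, sampling_interval),
       annotation = activity_annotation(ann))
}

#' Render radar sweeps from a chest trajectory
#'
#' Forward model of the pulse-coherent radar: each frame shows an amplitude
#' peak at the range bin nearest the instantaneous chest distance with a
#' Gaussian spatial falloff, and a wrapped phase equal to
#' `(4 * pi * f * d(t) / c) mod 2*pi` plus Gaussian phase noise.  Chest
#' distance is `baseline_distance` plus the (expiration-positive)
#' displacement: the chest recedes from a front-mounted radar while
#' exhaling.
#'
#' @param trace A [displacement_trace()] sampled at the radar frame interval.
#' @param config A [radar_config()].
#' @param profile A [subject_profile()] supplying standoff and phase noise,
#'   or `NULL` to use the explicit arguments.
#' @param baseline_distance Radar-to-chest standoff, metres.
#' @param phase_noise_sd Phase noise standard deviation, degrees.
#' @param amplitude_noise_sd Additive amplitude noise (peak height is 1).
#' @param falloff_bins Standard deviation of the spatial amplitude falloff,
#'   in range bins.
#' @param seed Seed for the rendering noise.
#' @return A [sweep_series()].
#' @export
render_sweeps <- function(trace, config = radar_config(),
                          profile = NULL,
                          baseline_distance = profile$baseline_distance,
                          phase_noise_sd = profile$phase_noise_sd %||% 6.1,
                          amplitude_noise_sd = 0.02,
                          falloff_bins = 3,
                          seed = profile$seed) {
  if (!inherits(trace, "displacement_trace")) {
    stop("`trace` must be a displacement_trace", call. = FALSE)
  }
  if (is.null(baseline_distance)) {
    stop("supply `baseline_distance` (or a profile carrying it)", call. = FALSE)
  }
  if (abs(trace$sampling_interval - config$frame_interval) > 1e-12) {
    stop("trace must be sampled at the radar frame interval", call. = FALSE)
  }
  sgn <- if (trace$expiration_positive) 1 else -1
  d <- baseline_distance + sgn * trace$values / 1000 # metres
  rng <- range_axis(config)
  if (any(d < config$range_start) || any(d > config$range_stop)) {
    stop("displacement drives the target outside the measured range",
         call. = FALSE)
  }
  sd_m <- falloff_bins * config$range_step
  amp <- exp(-outer(d, rng, "-")^2 / (2 * sd_m^2))
  ph_true <- wrap_2pi(4 * pi * config$center_frequency * d /
                        config$speed_of_light)
  ph <- matrix(ph_true, nrow = length(d), ncol = length(rng))
  if (amplitude_noise_sd > 0 || phase_noise_sd > 0) {
    nz <- with_seed(if (is.null(seed)) NULL else seed + 877L, {
      list(a = stats::rnorm(length(amp), 0, amplitude_noise_sd),
           p = stats::rnorm(length(ph), 0, deg2rad(phase_noise_sd)))
    })
    amp <- pmax(amp + nz$a, 0)
    ph <- wrap_2pi(ph + nz$p)
  }
  times <- trace$start_time + (seq_along(d) - 1L) * config$frame_interval
  sweep_series(amp, ph, times, rng)
}

#' Render a band-sensor reference channel
#'
#' Emulates a stretch-sensitive chest band: the reference output is a gain
#' times the chest displacement plus white noise, on the same sampling grid.
#' Output units are arbitrary (resistance-derived voltage in the real
#' sensor).
#'
#' @param trace A [displacement_trace()].
#' @param gain Multiplicative gain (a negative gain models a sensor wired
#'   with opposite polarity).
#' @param noise_sd White-noise standard deviation, output units.
#' @param seed Seed for the noise.
#' @return Numeric vector of reference samples, one per trace sample.
#' @export
render_band_signal <- function(trace, gain = 1, noise_sd = 0, seed = NULL) {
  if (!inherits(trace, "displacement_trace")) {
    stop("`trace` must be a displacement_trace", call. = FALSE)
  }
  n <- length(trace$values)
  gain * trace$values +
    with_seed(if (is.null(seed)) NULL else seed + 599L,
              stats::rnorm(n, 0, noise_sd))
}

#' Simulate one trial end to end
#'
#' Convenience wrapper: generates the chest motion for one commanded trial,
#' renders the radar sweeps, and (optionally) runs the displacement
#' estimator on them so the returned trace is what the radar pipeline would
#' deliver.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [trial_schedule()]; defaults to [default_schedule()].
#' @param config A [radar_config()].
#' @param measure `"radar"` returns the radar-estimated displacement as
#'   `trace` (truth kept as `truth`); `"truth"` skips rendering and returns
#'   the true motion.
#' @param seed Seed; defaults to the profile's.
#' @return A list with `trace`, `annotation`, `truth`, and (for
#'   `measure = "radar"`) `sweeps`.
#' @export
simulate_trial <- function(profile, schedule = default_schedule(profile),
                           config = radar_config(),
                           measure = c("radar", "truth"),
                           seed = profile$seed) {
  measure <- match.arg(measure)
  motion <- generate_motion(profile, schedule,
                            sampling_interval = config$frame_interval,
                            seed = seed)
  if (measure == "truth") {
    return(list(trace = motion$trace, annotation = motion$annotation,
                truth = motion$trace))
  }
  sweeps <- render_sweeps(motion$trace, config, profile = profile, seed = seed)
  est <- estimate_displacement(sweeps, config)
  list(trace = est, annotation = motion$annotation,
       truth = motion$trace, sweeps = sweeps)
}

#' Simulate a cohort of subjects
#'
#' Generates `trials_per_subject` commanded trials for each of `n_subjects`
#' synthetic subjects (each with its own physiology drawn from
#' [subject_profile()] ranges) and returns recordings ready for
#' [build_dataset()].
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Trials per subject (the collection protocol
#'   used ten).
#' @param seed Master seed; per-subject and per-trial seeds are derived from
#'   it.
#' @param config A [radar_config()].
#' @param measure Passed to [simulate_trial()]: `"radar"` (full pipeline) or
#'   `"truth"` (skip rendering; fast).
#' @param profile_args Named list of overrides passed to every
#'   [subject_profile()] call (e.g. `list(motion_noise_sd = 0)`).
#' @return A list of recordings, each `list(trace, annotation, subject)`.
#' @export
simulate_cohort <- function(n_subjects, trials_per_subject = 10, seed = 1,
                            config = radar_config(),
                            measure = c("radar", "truth"),
                            profile_args = list()) {
  measure <- match.arg(measure)
  recordings <- vector("list", n_subjects * trials_per_subject)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    subj_seed <- (seed * 1009L + s * 7919L) %% 2147483629L
    profile <- do.call(subject_profile,
                       c(list(seed = subj_seed), profile_args))
    for (tr in seq_len(trials_per_subject)) {
      trial_seed <- (subj_seed + tr * 104729L) %% 2147483629L
      sim <- simulate_trial(profile, config = config, measure = measure,
                            seed = trial_seed)
      k <- k + 1L
      recordings[[k]] <- list(trace = sim$trace,
                              annotation = sim$annotation,
                              subject = sprintf("S%02d", s))
    }
  }
  recordings
}
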