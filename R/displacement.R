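#' Select the target range bin
#'
#' Per frame, the chest shows up as the bin with the maximum reflected
#' amplitude; to resist per-frame outliers the target bin is the *mode* of
#' those per-frame argmax indices over the whole extracted interval (posture
#' is assumed fixed within it).  Ties in a frame's argmax and ties in the
#' mode both resolve to the lowest bin index.
#'
#' @param sweeps A [sweep_series()].
#' @return A single 1-based bin index into the range axis.
#' @export
select_range_bin <- function(sweeps) {
  if (!inherits(sweeps, "sweep_series")) stop("`sweeps` must be a sweep_series", call. = FALSE)
  if (nrow(sweeps$amplitude) < 1L) stop("empty sweep series", call. = FALSE)
  idx <- max.col(sweeps$amplitude, ties.method = "first")
  counts <- tabulate(idx, nbins = ncol(sweeps$amplitude))
  which.max(counts) # first (= lowest) index among tied modes
}

#' Extract the wrapped phase at one range bin
#'
#' @param sweeps A [sweep_series()].
#' @param bin 1-based bin index.
#' @return Numeric vector of wrapped phases in `[0, 2*pi)`, one per frame.
#' @export
extract_phase <- function(sweeps, bin) {
  if (!inherits(sweeps, "sweep_series")) stop("`sweeps` must be a sweep_series", call. = FALSE)
  if (length(bin) != 1L || bin < 1L || bin > ncol(sweeps$phase)) {
    stop("`bin` out of range", call. = FALSE)
  }
  sweeps$phase[, bin]
}

#' Unwrap a phase series
#'
#' Phase is observed modulo `2*pi`; a jump whose magnitude strictly exceeds
#' `pi` between consecutive frames is taken as a wrap crossing and corrected
#' by `2*pi` (a difference of exactly `pi` is left alone).  The first value
#' is unchanged; the output is elementwise congruent to the input modulo
#' `2*pi`, and all successive output differences have magnitude at most
#' `pi`.
#'
#' @param phases Numeric vector of wrapped phases in `[0, 2*pi)`.
#' @return Numeric vector of unwrapped phases.
#' @examples
#' unwrap_phase(c(0.10, 6.20)) # second value corrected by -2*pi
#' @export
unwrap_phase <- function(phases) {
  if (length(phases) == 0L) stop("`phases` must be nonempty", call. = FALSE)
  if (length(phases) == 1L) return(phases)
  d <- diff(phases) # in (-2*pi, 2*pi) for wrapped input
  d <- d - 2 * pi * (d > pi) + 2 * pi * (d < -pi)
  phases[1L] + cumsum(c(0, d))
}

#' Convert a phase change to a distance change
#'
#' Inverts the pulse-coherent radar sensitivity relation
#' `delta_phi = 4 * pi * delta_R * f / c`: a phase change maps linearly to a
#' radial distance change, with sensitivity proportional to the carrier
#' frequency (at 60 GHz, 1 mm of motion is about 144 degrees of phase; the
#' sensor's 6.1 degree phase noise floor corresponds to about 42 um).
#'
#' @param delta_phi Phase change(s), radians.
#' @param config A [radar_config()] supplying `center_frequency` and
#'   `speed_of_light`.
#' @return Distance change(s) in metres (same sign as `delta_phi`).
#' @examples
#' phase_to_displacement(144 * pi / 180,
#'                       radar_config(center_frequency = 60e9)) # ~1e-3 m
#' @export
phase_to_displacement <- function(delta_phi, config = radar_config()) {
  if (config$center_frequency <= 0) stop("frequency must be positive", call. = FALSE)
  if (any(!is.finite(delta_phi))) stop("`delta_phi` must be finite", call. = FALSE)
  delta_phi * config$speed_of_light / (4 * pi * config$center_frequency)
}

#' Forward phase sensitivity
#'
#' The forward direction of the same relation: the wrapped-free phase change
#' produced by a radial distance change.
#'
#' @param delta_r Distance change(s), metres.
#' @inheritParams phase_to_displacement
#' @return Phase change(s), radians.
#' @export
displacement_to_phase <- function(delta_r, config = radar_config()) {
  if (config$center_frequency <= 0) stop("frequency must be positive", call. = FALSE)
  4 * pi * delta_r * config$center_frequency / config$speed_of_light
}

#' Estimate chest displacement from a sweep series
#'
#' The composite estimator: select the modal argmax-amplitude range bin,
#' extract its wrapped phase, unwrap, and convert phase increments to
#' distance via the radar sensitivity relation.  The trace is anchored at 0
#' for the first frame (only distance *changes* are meaningful) and no
#' filtering is applied.  Under the expiration-positive convention an
#' increase in radar-to-chest distance (the chest receding while exhaling)
#' is positive.
#'
#' Recovery is exact only while the per-frame true motion stays below a
#' quarter wavelength (`c / (4 f)`, about 1.24 mm per frame at 60.5 GHz);
#' faster motion wraps by a full cycle and aliases.
#'
#' @param sweeps A [sweep_series()].
#' @param config A [radar_config()]; its `center_frequency` (default
#'   60.5 GHz, the sensor's centre frequency) is used in the conversion.
#' @param expiration_positive If `TRUE` (default), report distance increase
#'   as positive displacement.
#' @return A [displacement_trace()] in millimetres.
#' @export
estimate_displacement <- function(sweeps, config = radar_config(),
                                  expiration_positive = TRUE) {
  bin <- select_range_bin(sweeps)
  ph <- unwrap_phase(extract_phase(sweeps, bin))
  dr_mm <- phase_to_displacement(ph - ph[1L], config) * 1000
  if (!expiration_positive) dr_mm <- -dr_mm
  dt <- if (length(sweeps$time) > 1L) sweeps$time[2L] - sweeps$time[1L]
        else config$frame_interval
  displacement_trace(dr_mm,
                     sampling_interval = dt,
                     start_time = sweeps$time[1L],
                     expiration_positive = expiration_positive)
}
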