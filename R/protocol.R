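# Stimulation protocol: phase/time conversion, ramped per-channel
# waveforms, and plan export.  Channel k delivers
# env(t) * |x_k| * cos(2 pi f t + phi_k); because the complex currents sum
# to zero, the instantaneous cross-channel sum is zero at every sample.

#' Convert a phase delay to a time delay
#'
#' `(phase / 360) * (1000 / frequency)` milliseconds; e.g. a 90 degree
#' delay at 80 Hz is 3.125 ms.
#'
#' @param phase_deg phase delay in degrees.
#' @param frequency_hz carrier frequency (> 0).
#' @return delay in milliseconds.
#' @examples
#' phase_to_time(90, 80)
#' @export
phase_to_time <- function(phase_deg, frequency_hz) {
  if (any(frequency_hz <= 0)) abort("frequency must be > 0")
  phase_deg / 360 * 1000 / frequency_hz
}

#' Build a stimulation plan
#'
#' @param montage a `montage`.
#' @param duration_s total duration (s); must exceed twice the ramp.
#' @param ramp_s linear ramp-up and ramp-down duration (default 30 s).
#' @param sample_rate_hz waveform sample rate (default 10 kHz; must be at
#'   least 20 times the carrier frequency).
#' @param impedance_abort_kohm hardware abort threshold recorded as
#'   metadata only (default 20).
#' @return a `stimulation_plan`.
#' @export
stimulation_plan <- function(montage, duration_s, ramp_s = 30,
                             sample_rate_hz = 10000,
                             impedance_abort_kohm = 20) {
  f <- attr(montage, "frequency_hz")
  if (2 * ramp_s >= duration_s) abort("duration must exceed twice the ramp")
  if (sample_rate_hz < 20 * f) {
    abort("sample rate %.3g Hz too low for a %.3g Hz carrier (need >= 20x)",
          sample_rate_hz, f)
  }
  structure(
    list(montage = montage, frequency_hz = f, duration_s = duration_s,
         ramp_s = ramp_s, sample_rate_hz = sample_rate_hz,
         impedance_abort_kohm = impedance_abort_kohm),
    class = "stimulation_plan"
  )
}

#' Render the per-channel current waveforms
#'
#' @param plan a `stimulation_plan`.
#' @return list with `time_s` and `currents_mA` (samples x channels,
#'   channel names from the montage).
#' @export
render_waveforms <- function(plan) {
  m <- plan$montage
  t <- seq(0, plan$duration_s, by = 1 / plan$sample_rate_hz)
  env <- pmin(1, pmin(t, plan$duration_s - t) / plan$ramp_s)
  env[env < 0] <- 0
  wt <- 2 * pi * plan$frequency_hz * t
  cur <- vapply(seq_len(nrow(m)), function(k) {
    env * m$amplitude_mA[k] * cos(wt + deg2rad(m$phase_deg[k]))
  }, numeric(length(t)))
  colnames(cur) <- m$electrode
  list(time_s = t, currents_mA = cur)
}

#' Write waveforms as wide-format CSV
#'
#' First column `time_s`, one column per electrode (mA).
#'
#' @param waveforms output of [render_waveforms()].
#' @param path output path.
#' @export
write_waveform_csv <- function(waveforms, path) {
  utils::write.csv(
    data.frame(time_s = waveforms$time_s, waveforms$currents_mA,
               check.names = FALSE),
    path, row.names = FALSE
  )
  invisible(path)
}
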