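#' Morphology parameters for a simulated subject
#'
#' Bundles the knobs controlling the simulated waveforms. The defaults describe
#' a resting adult: ~15 breaths/min with mild cycle-to-cycle variability,
#' chest-wall acceleration excursions of ~0.05 g, and a small chest-to-abdomen
#' phase offset. Event morphology multipliers are relative to
#' `breath_amplitude`; the obstructive-apnea phase shift defaults to pi so
#' thorax and abdomen move in anti-phase (paradoxical breathing).
#'
#' @param breathing_rate Breaths per minute (> 0).
#' @param breath_amplitude Respiratory acceleration amplitude on the dominant
#'   (z) accelerometer axis, in g.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise on the
#'   accelerometer channels, in g (gyro noise scales with `gyro_gain`).
#' @param phase_offset_abdomen Maximum abdomen-vs-chest phase offset during
#'   normal breathing, radians.
#' @param osa_phase_shift Abdomen phase shift during obstructive apnea,
#'   radians in (0, 2*pi); pi gives full anti-phase motion.
#' @param rate_jitter_sd Log-scale SD of per-cycle breathing-period jitter.
#' @param amp_jitter_sd Log-scale SD of per-cycle amplitude jitter.
#' @param harmonic2 Relative amplitude of the second respiratory harmonic.
#' @param gyro_gain Gyroscope excursion per g of accelerometer excursion,
#'   deg/s per g.
#' @param event_amplitude_scales Named multipliers (vs `breath_amplitude`)
#'   for the five event classes.
#' @return An object of class `subject_profile`.
#' @export
#' @examples
#' p <- subject_profile(breathing_rate = 12)
#' p$breathing_rate
subject_profile <- function(breathing_rate = 15,
                            breath_amplitude = 0.05,
                            noise_sd = 0.004,
                            phase_offset_abdomen = 0.2,
                            osa_phase_shift = pi,
                            rate_jitter_sd = 0.04,
                            amp_jitter_sd = 0.08,
                            harmonic2 = 0.25,
                            gyro_gain = 40,
                            event_amplitude_scales = c(csa = 0.08, cough = 4,
                                                       osa = 1.3, sigh = 2.5,
                                                       yawn = 2.5)) {
  assert_scalar_number(breathing_rate, "breathing_rate")
  if (breathing_rate <= 0) stop_bd("`breathing_rate` must be > 0")
  if (noise_sd < 0) stop_bd("`noise_sd` must be >= 0")
  if (osa_phase_shift <= 0 || osa_phase_shift >= 2 * pi) {
    stop_bd("`osa_phase_shift` must lie in (0, 2*pi)")
  }
  need <- setdiff(EVENT_CLASSES[-1L], names(event_amplitude_scales))
  if (length(need)) stop_bd("event_amplitude_scales missing class(es): %s",
                            paste(need, collapse = ", "))
  structure(list(breathing_rate = breathing_rate,
                 breath_amplitude = breath_amplitude,
                 noise_sd = noise_sd,
                 phase_offset_abdomen = phase_offset_abdomen,
                 osa_phase_shift = osa_phase_shift,
                 rate_jitter_sd = rate_jitter_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 harmonic2 = harmonic2,
                 gyro_gain = gyro_gain,
                 event_amplitude_scales = event_amplitude_scales),
            class = "subject_profile")
}

# Per-channel respiratory gain: how strongly each channel reflects the
# breathing waveform (z accelerometer axes dominate; gyro responds mostly
# about the pitch (x) axis). Ordered as channel_layout()$names.
channel_gains <- function(profile) {
  accel <- c(x = 0.35, y = 0.20, z = 1.00)
  gyro <- c(x = 1.00, y = 0.50, z = 0.30) * profile$gyro_gain
  g <- c(accel, gyro, accel, gyro)
  names(g) <- channel_layout()$names
  g
}

# Constant sensor baselines: gravity (~1 g) on each z accelerometer axis,
# zero elsewhere.
channel_baselines <- function() {
  b <- rep(0, 12L)
  names(b) <- channel_layout()$names
  b[c("chest_accel_z", "abdomen_accel_z")] <- 1
  b
}
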