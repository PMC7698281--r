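# Synthetic 12-channel IMU breathing signals.
#
# The waveform model is deliberately simple: each channel is a constant sensor
# baseline (gravity on the z accelerometer axes) plus a quasi-sinusoidal
# respiratory component (per-cycle period and amplitude jitter, one second
# harmonic) scaled by a per-channel gain, plus white Gaussian noise. Event
# clips reshape the respiratory component per class: near-flat for central
# apnea, anti-phase abdomen motion for obstructive apnea, short 10-25 Hz
# bursts for cough, one oversized breath for sigh, and one slow large
# inspiration for yawn.

# Draw per-cycle period/amplitude jitter for a stretch of breathing.
resp_cycles <- function(total_s, rate_bpm, rate_jitter_sd, amp_jitter_sd) {
  mean_period <- 60 / rate_bpm
  n_guess <- ceiling(total_s / mean_period) + 4L
  repeat {
    durs <- mean_period * exp(rnorm(n_guess, 0, rate_jitter_sd))
    if (sum(durs) >= total_s + mean_period) break
    n_guess <- n_guess + 4L
  }
  list(bounds = c(0, cumsum(durs)),
       amps = exp(rnorm(n_guess, 0, amp_jitter_sd)))
}

# Evaluate the quasi-sinusoid at times `t` with a site phase shift.
resp_wave <- function(t, cyc, phase_shift, harmonic2) {
  k <- length(cyc$bounds)
  ph <- approx(cyc$bounds, 2 * pi * (seq_len(k) - 1L), xout = t, rule = 2)$y
  a <- cyc$amps[pmin(pmax(findInterval(t, cyc$bounds), 1L), length(cyc$amps))]
  a * (sin(ph + phase_shift) + harmonic2 * sin(2 * (ph + phase_shift)))
}

# Assemble the T x 12 matrix from chest/abdomen unit respiratory components
# (already including any event morphology) plus optional broadband bursts.
assemble_channels <- function(chest, abdomen, profile, burst = NULL) {
  n <- length(chest)
  gains <- channel_gains(profile)
  base <- channel_baselines()
  comp <- cbind(matrix(chest, n, 6L), matrix(abdomen, n, 6L))
  data <- comp * rep(gains * profile$breath_amplitude, each = n)
  if (!is.null(burst)) {
    # whole-torso broadband transient, slightly attenuated at the abdomen
    bmat <- cbind(matrix(burst, n, 6L), matrix(0.8 * burst, n, 6L))
    data <- data + bmat * rep(gains * profile$breath_amplitude, each = n)
  }
  data <- data + rep(base, each = n)
  if (profile$noise_sd > 0) {
    noise_sd <- profile$noise_sd * rep(c(1, 1, 1, rep(profile$gyro_gain, 3L)), 2L)
    data <- data + matrix(rnorm(n * 12L), n, 12L) * rep(noise_sd, each = n)
  }
  colnames(data) <- channel_layout()$names
  data
}

#' Simulate normal breathing
#'
#' Generates an annotated 12-channel recording of quiet breathing: a
#' quasi-sinusoid at the profile's breathing rate with small cycle-to-cycle
#' rate/amplitude jitter, chest and abdomen respiratory components in phase up
#' to `phase_offset_abdomen`, constant gravity offsets on the z accelerometer
#' axes, and additive Gaussian noise.
#'
#' @param duration_s Duration in seconds (> 0); the recording has
#'   `round(duration_s * 125)` samples.
#' @param profile A [subject_profile()].
#' @param seed Integer seed; identical `(profile, seed)` give identical output.
#' @param subject_id Subject identifier stored in the recording.
#' @return A `recording` annotated as a single `normal` span.
#' @export
#' @examples
#' rec <- simulate_normal_breathing(30, seed = 1)
#' nrow(rec$data)  # 3750
simulate_normal_breathing <- function(duration_s, profile = subject_profile(),
                                      seed = 1L, subject_id = "sim") {
  assert_scalar_number(duration_s, "duration_s")
  if (duration_s <= 0) stop_bd("`duration_s` must be positive")
  n <- as.integer(round(duration_s * SAMPLE_RATE))
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / SAMPLE_RATE
    cyc <- resp_cycles(duration_s, profile$breathing_rate,
                       profile$rate_jitter_sd, profile$amp_jitter_sd)
    chest <- resp_wave(t, cyc, 0, profile$harmonic2)
    abdomen <- resp_wave(t, cyc, -profile$phase_offset_abdomen, profile$harmonic2)
    data <- assemble_channels(chest, abdomen, profile)
    new_recording(data, subject_id = subject_id,
                  annotations = data.frame(label = "normal", start_sample = 0L,
                                           end_sample = n,
                                           stringsAsFactors = FALSE))
  })
}

# Per-class duration bounds (seconds). Cough/sigh/yawn/osa never exceed 14 s;
# a yawn is by definition a slow (>= 4 s) maneuver.
event_duration_bounds <- function(label) {
  switch(label,
         csa = c(1, Inf),
         cough = c(0.2, 14),
         osa = c(1, 14),
         sigh = c(1, 14),
         yawn = c(4, 14),
         stop_bd("unknown event label '%s'", label))
}

#' Simulate a single breathing-event clip
#'
#' Generates a standalone annotated clip of one event class with a fixed
#' morphology contract: `csa` has near-zero respiratory-band power; `osa`
#' keeps respiratory motion but with the abdomen shifted by
#' `profile$osa_phase_shift` (anti-phase by default) relative to the chest;
#' `cough` contains one or more 10-25 Hz bursts with amplitude at least 3x the
#' normal breath amplitude; `sigh` is a single breath of at least 2x
#' amplitude; `yawn` is a single slow (>= 4 s) large inspiration.
#'
#' @param label One of `"csa"`, `"cough"`, `"osa"`, `"sigh"`, `"yawn"`.
#' @param duration_s Clip duration in seconds; cough/sigh/yawn/osa must not
#'   exceed 14 s and a yawn must last at least 4 s.
#' @param profile A [subject_profile()].
#' @param seed Integer seed.
#' @param subject_id Subject identifier stored in the recording.
#' @return A `recording` annotated as a single span of `label`.
#' @export
#' @examples
#' clip <- simulate_event_clip("cough", 1, seed = 3)
#' nrow(clip$data)  # 125
simulate_event_clip <- function(label, duration_s, profile = subject_profile(),
                                seed = 1L, subject_id = "sim") {
  if (!label %in% EVENT_CLASSES[-1L]) {
    stop_bd("`label` must be one of: %s", paste(EVENT_CLASSES[-1L], collapse = ", "))
  }
  assert_scalar_number(duration_s, "duration_s")
  bounds <- event_duration_bounds(label)
  if (duration_s < bounds[1] || duration_s > bounds[2]) {
    stop_bd("duration %.2f s outside the admissible range [%g, %g] s for '%s'",
            duration_s, bounds[1], bounds[2], label)
  }
  n <- as.integer(round(duration_s * SAMPLE_RATE))
  sc <- profile$event_amplitude_scales
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / SAMPLE_RATE
    burst <- NULL
    if (label == "csa") {
      # breath hold at functional residual capacity: residual micro-motion only
      cyc <- resp_cycles(duration_s, profile$breathing_rate,
                         profile$rate_jitter_sd, profile$amp_jitter_sd)
      chest <- sc[["csa"]] * resp_wave(t, cyc, 0, profile$harmonic2)
      abdomen <- sc[["csa"]] *
        resp_wave(t, cyc, -profile$phase_offset_abdomen, profile$harmonic2)
    } else if (label == "osa") {
      # continued (labored, slightly faster) effort against an occluded airway:
      # thorax and abdomen move against each other
      cyc <- resp_cycles(duration_s, profile$breathing_rate * 1.15,
                         profile$rate_jitter_sd, profile$amp_jitter_sd)
      chest <- sc[["osa"]] * resp_wave(t, cyc, 0, profile$harmonic2)
      abdomen <- sc[["osa"]] *
        resp_wave(t, cyc, -profile$osa_phase_shift, profile$harmonic2)
    } else if (label == "cough") {
      # low-level residual breathing with 10-25 Hz expulsive bursts
      cyc <- resp_cycles(duration_s, profile$breathing_rate,
                         profile$rate_jitter_sd, profile$amp_jitter_sd)
      chest <- 0.15 * resp_wave(t, cyc, 0, profile$harmonic2)
      abdomen <- chest
      n_bursts <- max(1L, round(duration_s))
      centers <- ((seq_len(n_bursts) - 0.5) / n_bursts) * duration_s +
        runif(n_bursts, -0.05, 0.05) * duration_s / n_bursts
      freqs <- runif(n_bursts, 12, 20)
      width <- min(0.3, duration_s * 0.6)
      burst <- rep(0, n)
      for (b in seq_len(n_bursts)) {
        u <- t - centers[b]
        env <- ifelse(abs(u) < width / 2, 0.5 * (1 + cos(2 * pi * u / width)), 0)
        burst <- burst + sc[["cough"]] * env * sin(2 * pi * freqs[b] * u)
      }
    } else if (label == "sigh") {
      # one oversized breath spanning the clip
      phase <- 2 * pi * t / duration_s
      chest <- sc[["sigh"]] * sin(phase)
      abdomen <- sc[["sigh"]] * sin(phase - profile$phase_offset_abdomen)
    } else if (label == "yawn") {
      # single slow large inspiration-expiration bump
      chest <- sc[["yawn"]] * 0.5 * (1 - cos(2 * pi * t / duration_s))
      abdomen <- sc[["yawn"]] * 0.5 *
        (1 - cos(2 * pi * pmax(t - 0.05, 0) / duration_s))
    }
    data <- assemble_channels(chest, abdomen, profile, burst = burst)
    new_recording(data, subject_id = subject_id,
                  annotations = data.frame(label = label, start_sample = 0L,
                                           end_sample = n,
                                           stringsAsFactors = FALSE))
  })
}

#' Simulate a full acquisition session for one subject
#'
#' Emulates the acquisition protocol: 300 s of normal breathing, one 30-s
#' central-apnea breath hold, and five repetitions each of yawn, cough, sigh
#' and obstructive apnea (Mueller maneuver), in seeded-random order, separated
#' by 5-15 s gaps of normal breathing. Event durations are drawn per
#' repetition from class-typical ranges.
#'
#' @param profile A [subject_profile()].
#' @param seed Integer seed; the whole session is a deterministic function of
#'   `(profile, seed)`.
#' @param subject_id Subject identifier.
#' @return An annotated `recording` containing 1 csa and 5 each of yawn,
#'   cough, sigh and osa annotations plus normal spans totalling >= 300 s.
#' @export
#' @examples
#' ses <- simulate_subject_session(seed = 42, subject_id = "S042")
#' table(ses$annotations$label)
simulate_subject_session <- function(profile = subject_profile(), seed = 1L,
                                     subject_id = "sim") {
  with_seed(seed, {
    events <- data.frame(
      label = c("csa", rep(c("yawn", "cough", "sigh", "osa"), each = 5L)),
      stringsAsFactors = FALSE)
    events$duration <- c(30,
                         runif(5, 4.5, 8),    # yawn
                         runif(5, 1.2, 2.5),  # cough
                         runif(5, 2.5, 5),    # sigh
                         runif(5, 6, 12))     # osa
    items <- rbind(data.frame(label = "normal", duration = 300,
                              stringsAsFactors = FALSE), events)
    items <- items[sample.int(nrow(items)), , drop = FALSE]
    gap_durs <- runif(nrow(items) - 1L, 5, 15)
    piece_seeds <- draw_subseeds(2L * nrow(items))

    pieces <- vector("list", 2L * nrow(items) - 1L)
    labels <- character(length(pieces))
    k <- 0L
    for (i in seq_len(nrow(items))) {
      k <- k + 1L
      lab <- items$label[i]
      labels[k] <- lab
      pieces[[k]] <- if (lab == "normal") {
        simulate_normal_breathing(items$duration[i], profile,
                                  seed = piece_seeds[2L * i - 1L])$data
      } else {
        simulate_event_clip(lab, items$duration[i], profile,
                            seed = piece_seeds[2L * i - 1L])$data
      }
      if (i < nrow(items)) {
        k <- k + 1L
        labels[k] <- "normal"
        pieces[[k]] <- simulate_normal_breathing(gap_durs[i], profile,
                                                 seed = piece_seeds[2L * i])$data
      }
    }
    lens <- vapply(pieces, nrow, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens
    new_recording(do.call(rbind, pieces), subject_id = subject_id,
                  annotations = data.frame(label = labels,
                                           start_sample = as.integer(starts),
                                           end_sample = as.integer(ends),
                                           stringsAsFactors = FALSE))
  })
}
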