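# Synthetic signal generator: sample-count arithmetic, waveform contracts,
# determinism, and event morphologies.

test_that("sample counts equal round(duration * 125) exactly", {
  expect_equal(nrow(simulate_normal_breathing(30, seed = 1)$data), 3750L)
  expect_equal(nrow(simulate_event_clip("cough", 1, seed = 1)$data), 125L)
  expect_equal(nrow(simulate_event_clip("csa", 10, seed = 1)$data), 1250L)
  for (d in c(1.5, 2.37, 7.991, 13.2)) {
    expect_equal(nrow(simulate_event_clip("sigh", d, seed = 2)$data),
                 round(d * 125))
  }
})

test_that("zero amplitude and zero noise give exactly constant channels", {
  p <- subject_profile(breath_amplitude = 0, noise_sd = 0)
  rec <- simulate_normal_breathing(5, p, seed = 3)
  for (j in seq_len(12)) {
    expect_equal(diff(range(rec$data[, j])), 0)
  }
  # gravity baseline on z accelerometer axes, zero elsewhere
  expect_equal(unname(rec$data[1, "chest_accel_z"]), 1)
  expect_equal(unname(rec$data[1, "chest_accel_x"]), 0)
  expect_equal(unname(rec$data[1, "abdomen_accel_z"]), 1)
})

test_that("dominant periodogram frequency matches the breathing rate", {
  p <- subject_profile(breathing_rate = 15, rate_jitter_sd = 0.02, noise_sd = 0.001)
  rec <- simulate_normal_breathing(60, p, seed = 4)
  peak <- oracle_peak_freq(rec$data[, "chest_accel_z"])
  expect_lt(abs(peak - 0.25), 1 / 60 + 1e-9)  # one frequency bin
})

test_that("generation is deterministic in (profile, seed) and finite", {
  a <- simulate_normal_breathing(10, seed = 5)
  b <- simulate_normal_breathing(10, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$data, simulate_normal_breathing(10, seed = 6)$data))
  expect_true(all(is.finite(a$data)))
  c1 <- simulate_event_clip("osa", 8, seed = 5)
  c2 <- simulate_event_clip("osa", 8, seed = 5)
  expect_identical(c1, c2)
})

test_that("csa clips have under 5% of normal respiratory-band power", {
  p <- subject_profile()
  for (seed in 1:5) {
    csa <- simulate_event_clip("csa", 10, p, seed = seed)
    nb <- simulate_normal_breathing(10, p, seed = seed + 50)
    ratio <- oracle_band_power(csa$data[, "chest_accel_z"]) /
      oracle_band_power(nb$data[, "chest_accel_z"])
    expect_lt(ratio, 0.05)
  }
})

test_that("osa clips show anti-phase chest vs abdomen respiratory motion", {
  for (seed in 1:10) {
    clip <- simulate_event_clip("osa", 10, seed = seed)
    r <- cor(oracle_bandpass(clip$data[, "chest_accel_z"]),
             oracle_bandpass(clip$data[, "abdomen_accel_z"]))
    expect_lt(r, 0)
  }
  # normal breathing stays in phase
  nb <- simulate_normal_breathing(10, seed = 1)
  r0 <- cor(oracle_bandpass(nb$data[, "chest_accel_z"]),
            oracle_bandpass(nb$data[, "abdomen_accel_z"]))
  expect_gt(r0, 0.8)
})

test_that("cough clips carry large 10-25 Hz bursts", {
  p <- subject_profile()
  clip <- simulate_event_clip("cough", 2, p, seed = 9)
  z <- clip$data[, "chest_accel_z"]
  expect_gte(max(abs(z - median(z))), 3 * p$breath_amplitude)
  burst_band <- oracle_band_power(z, lo = 10, hi = 25)
  resp_band <- oracle_band_power(z, lo = 0.1, hi = 0.7)
  expect_gt(burst_band, resp_band)
})

test_that("sigh is a single oversized breath and yawn a slow inspiration", {
  p <- subject_profile()
  sigh <- simulate_event_clip("sigh", 4, p, seed = 2)
  expect_gte(max(abs(sigh$data[, "chest_accel_z"] - 1)), 2 * p$breath_amplitude)
  yawn <- simulate_event_clip("yawn", 6, p, seed = 2)
  z <- yawn$data[, "chest_accel_z"]
  expect_gte(max(abs(z - 1)), 2 * p$breath_amplitude)
  # energy concentrated below the normal respiratory rate: slow maneuver
  expect_gt(oracle_band_power(z, lo = 0.05, hi = 0.2),
            oracle_band_power(z, lo = 0.3, hi = 1))
})

test_that("invalid durations and labels are rejected with messages", {
  expect_error(simulate_normal_breathing(-1), "positive")
  expect_error(simulate_event_clip("cough", 20, seed = 1), "admissible range")
  expect_error(simulate_event_clip("yawn", 3, seed = 1), "admissible range")
  expect_error(simulate_event_clip("normal", 5, seed = 1), "must be one of")
  expect_error(simulate_event_clip("snore", 5, seed = 1), "must be one of")
})

test_that("a subject session follows the acquisition protocol", {
  ses <- fx_session()
  counts <- table(ses$annotations$label)
  expect_equal(unname(counts["csa"]), 1L)
  for (cl in c("yawn", "cough", "sigh", "osa")) {
    expect_equal(unname(counts[[cl]]), 5L)
  }
  normal <- ses$annotations[ses$annotations$label == "normal", ]
  expect_gte(sum(normal$end_sample - normal$start_sample) / 125, 300)
  # valid, sorted, non-overlapping annotations
  expect_silent(validate_recording(ses))
  # determinism: same seed gives identical sessions
  expect_identical(ses, simulate_subject_session(seed = 101L, subject_id = "T01"))
})

test_that("a band-power matched filter separates csa from normal perfectly", {
  p <- subject_profile()
  normal_power <- vapply(1:50, function(s) {
    oracle_band_power(simulate_normal_breathing(10, p, seed = s)$data[, "chest_accel_z"])
  }, numeric(1))
  csa_power <- vapply(1:50, function(s) {
    oracle_band_power(simulate_event_clip("csa", 10, p, seed = 1000 + s)$data[, "chest_accel_z"])
  }, numeric(1))
  # complete separation implies 100% accuracy for a threshold classifier
  expect_lt(max(csa_power), min(normal_power))
})
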