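# Event-pool extraction, injection-plan drawing, splicing and smoothing.

test_that("pool counts follow the session protocol (5 per class per session)", {
  pool1 <- extract_event_pool(list(fx_session()))
  expect_equal(unname(lengths(pool1$clips_by_class)[c("csa", "cough", "sigh", "yawn", "osa")]),
               c(1L, 5L, 5L, 5L, 5L))
  pool3 <- fx_pool()
  expect_equal(length(pool3$clips_by_class$cough), 3L * 5L)
  expect_equal(length(pool3$clips_by_class$csa), 3L)
  # structure preservation: every clip keeps the 12 channels
  for (cls in names(pool3$clips_by_class)) {
    for (clip in pool3$clips_by_class[[cls]]) {
      expect_equal(ncol(clip$data), 12L)
      expect_gte(nrow(clip$data), 125L)
    }
  }
})

test_that("recordings without annotations are skipped with a warning", {
  bare <- new_recording(matrix(0, 250, 12), subject_id = "bare")
  expect_warning(pool <- extract_event_pool(list(bare, fx_session())), "skipped")
  expect_equal(length(pool$clips_by_class$cough), 5L)
})

test_that("single-event CSA durations come from {10, 20, 23}", {
  pool <- fx_pool()
  durs <- integer()
  for (s in 1:400) {
    e <- draw_injection_plan(1L, pool, seed = s)$entries
    if (e$label == "csa") durs <- c(durs, e$duration_s)
  }
  expect_gt(length(durs), 20)
  expect_true(all(durs %in% c(10L, 20L, 23L)))
})

test_that("two-event plans respect the 15-s halves and never overlap", {
  pool <- fx_pool()
  for (s in 1:400) {
    e <- draw_injection_plan(2L, pool, seed = s)$entries
    expect_equal(nrow(e), 2L)
    expect_lt(e$start_second[1], 15)
    expect_lte(e$start_second[1] + e$duration_s[1], 15)
    expect_gte(e$start_second[2], 15)
    expect_lte(e$start_second[2] + e$duration_s[2], 30)
    if (any(e$label == "csa")) {
      expect_true(all(e$duration_s[e$label == "csa"] %in% c(10L, 11L, 13L)))
    }
  }
})

test_that("plan drawing is seeded and the empty plan is empty", {
  pool <- fx_pool()
  expect_identical(draw_injection_plan(2L, pool, seed = 5L),
                   draw_injection_plan(2L, pool, seed = 5L))
  p0 <- draw_injection_plan(0L, pool, seed = 1L)
  expect_equal(nrow(p0$entries), 0L)
  base <- simulate_normal_breathing(30, seed = 77)$data
  seg <- inject_events(base, p0, pool)
  expect_identical(seg$data, base)
  expect_true(all(seg$labels == "normal"))
})

test_that("empty pools for a class are rejected at draw time", {
  pool <- fx_pool()
  pool$clips_by_class$yawn <- list()
  expect_error(
    for (s in 1:50) draw_injection_plan(1L, pool, seed = s),
    "empty for class 'yawn'")
})

test_that("empirical single-CSA duration distribution is uniform", {
  pool <- fx_pool()
  # plan seeds drawn from a parent stream, mirroring build_detection_dataset
  set.seed(99)
  seeds <- sample.int(.Machine$integer.max, 10000)
  durs <- vapply(seeds, function(s) {
    e <- draw_injection_plan(1L, pool, seed = s)$entries
    if (e$label == "csa") e$duration_s else NA_integer_
  }, integer(1))
  durs <- durs[!is.na(durs)]
  expect_gt(length(durs), 1500)
  # chi-square goodness of fit against the uniform over {10, 20, 23}
  tab <- table(factor(durs, levels = c(10, 20, 23)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("injection writes labels exactly over plan spans and keeps shape", {
  pool <- fx_pool()
  base <- simulate_normal_breathing(30, seed = 31)$data
  cough_idx <- which(vapply(pool$clips_by_class$cough, function(cl) {
    ceiling(nrow(cl$data) / 125) == 2
  }, logical(1)))[1]
  skip_if(is.na(cough_idx), "no 2-s cough clip in fixture pool")
  plan <- structure(list(entries = data.frame(label = "cough", start_second = 5L,
                                              duration_s = 2L,
                                              clip_index = cough_idx,
                                              stringsAsFactors = FALSE),
                         n_events = 1L),
                    class = "injection_plan")
  seg <- inject_events(base, plan, pool, seed = 2)
  expect_equal(dim(seg$data), c(3750L, 12L))
  expect_equal(seg$labels[6:7], c("cough", "cough"))
  expect_true(all(seg$labels[-(6:7)] == "normal"))
})

test_that("splice + smoothing matches a brute-force oracle bit-for-bit", {
  pool <- fx_pool()
  base <- simulate_normal_breathing(30, seed = 57)$data
  idx <- 2L
  clip <- pool$clips_by_class$sigh[[idx]]$data
  dur <- as.integer(ceiling(nrow(clip) / 125))
  start <- 8L
  plan <- structure(list(entries = data.frame(label = "sigh", start_second = start,
                                              duration_s = dur, clip_index = idx,
                                              stringsAsFactors = FALSE),
                         n_events = 1L),
                    class = "injection_plan")
  seg <- inject_events(base, plan, pool, seed = 3)

  # independent reconstruction: splice, then average each edge explicitly
  manual <- base
  s0 <- start * 125L
  rows <- (s0 + 1L):(s0 + nrow(clip))
  manual[rows, ] <- clip
  for (ch in 1:12) {
    manual[rows[1], ch] <- (clip[1, ch] + base[rows[1] - 1L, ch]) / 2
    manual[rows[length(rows)], ch] <-
      (clip[nrow(clip), ch] + base[rows[length(rows)] + 1L, ch]) / 2
  }
  expect_identical(seg$data, manual)
  expect_equal(seg$labels[(start + 1):(start + dur)], rep("sigh", dur))
})

test_that("boundary averaging follows the arithmetic rule per channel", {
  m <- matrix(rep(2, 10 * 12), 10, 12)
  m[4:6, ] <- 4                       # injected span, samples 4..6 (1-based)
  m[4, 3] <- 2                        # equal to neighbor on one channel
  out <- smooth_boundary(m, c(3L, 6L))
  expect_equal(out[4, 1], 3)          # (4 + 2) / 2
  expect_equal(out[4, 3], 2)          # mean of equals unchanged
  expect_equal(out[6, 1], 3)
  expect_equal(out[5, 1], 4)          # interior untouched
  # channels handled independently
  m2 <- matrix(seq_len(10 * 12), 10, 12)
  sm <- smooth_boundary(m2, c(3L, 6L))
  for (ch in 1:12) {
    expect_equal(sm[4, ch], (m2[4, ch] + m2[3, ch]) / 2)
    expect_equal(sm[6, ch], (m2[6, ch] + m2[7, ch]) / 2)
  }
  # spans touching an edge smooth only the interior side
  edge <- smooth_boundary(m2, c(0L, 4L))
  expect_equal(edge[1, 1], m2[1, 1])
  expect_equal(edge[4, 1], (m2[4, 1] + m2[5, 1]) / 2)
})

test_that("a csa clip shorter than the planned duration is a named error", {
  pool <- fx_pool()
  pool$clips_by_class$csa[[1]]$data <-
    pool$clips_by_class$csa[[1]]$data[1:1250, ]  # 10 s
  plan <- structure(list(entries = data.frame(label = "csa", start_second = 0L,
                                              duration_s = 20L, clip_index = 1L,
                                              stringsAsFactors = FALSE),
                         n_events = 1L),
                    class = "injection_plan")
  base <- simulate_normal_breathing(30, seed = 5)$data
  expect_error(inject_events(base, plan, pool), "shorter than the planned")
})
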