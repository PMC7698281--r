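# Architecture audits, probability normalization, training mechanics.

tiny_clf_cfg <- function(task = "multi") {
  classifier_config(task, scale = "desk", window_s = 1, conv_kernel = 5L,
                    conv_filters = rep(4L, 6), fc_widths = c(8L, 6L, 4L))
}

tiny_det_cfg <- function() {
  detector_config("desk", segment_s = 2L, first_kernel = 16L, block_kernel = 8L,
                  base_filters = 4L, stem_stride = 5L,
                  block_strides = c(5L, 5L, 1L, 1L))
}

rand_windows <- function(n, Tn = 125L, labels = NULL, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(data = matrix(rnorm(Tn * 12), Tn, 12),
         label = if (is.null(labels)) sample(EVENT_CLASSES, 1) else labels[i])
  })
}

rand_segments <- function(n, segment_s = 2L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    structure(list(data = matrix(rnorm(segment_s * 125 * 12), segment_s * 125, 12),
                   labels = sample(EVENT_CLASSES, segment_s, TRUE),
                   plan = NULL, segment_id = sprintf("r%03d", i)),
              class = "labeled_segment")
  })
}

test_that("classifier audit: 6 convolutional and 4 fully connected layers", {
  m <- build_classifier(classifier_config("binary", scale = "full"))
  expect_equal(m$n_conv, 6L)
  expect_equal(m$n_fc, 4L)
  expect_equal(m$input_shape, c(875L, 12L))
  expect_equal(m$flat_features, 10500L)
  expect_equal(m$config$l2, 0.1)
  mm <- build_classifier(classifier_config("multi", scale = "full"))
  expect_equal(mm$config$l2, 0.001)
  expect_equal(mm$layers$filters[mm$layers$name == "out"], 6L)
})

test_that("detector audit: stem + 4 doubling residual blocks, x125 downsampling", {
  m <- build_detector(detector_config("full"))
  blocks <- m$layers[m$layers$type == "residual_block", ]
  expect_equal(blocks$filters, c(64L, 128L, 256L, 512L))
  expect_equal(m$n_conv, 1L + 4L * 2L)
  expect_gt(m$n_params, 1e8)           # full scale: order 2e8 parameters
  expect_equal(m$layers$t_out[nrow(m$layers)], 30L)
  d <- build_detector(detector_config("desk"))
  expect_equal(d$input_shape[1L], d$config$per_second_outputs * 125L)
  expect_error(detector_config("desk", stem_stride = 2L), "downsampling")
})

test_that("probability outputs are normalized", {
  m <- breathdetect:::init_model_params(build_classifier(tiny_clf_cfg("multi")), 1L)
  X <- array(rnorm(125 * 3 * 12), c(125, 3, 12))
  P <- breathdetect:::classifier_forward(m, X)$prob
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
  b <- breathdetect:::init_model_params(build_classifier(tiny_clf_cfg("binary")), 1L)
  pb <- breathdetect:::classifier_forward(b, X)$prob
  expect_true(all(pb >= 0 & pb <= 1))
  d <- breathdetect:::init_model_params(build_detector(tiny_det_cfg()), 1L)
  Xd <- array(rnorm(250 * 2 * 12), c(250, 2, 12))
  Pd <- breathdetect:::detector_forward(d, Xd)$prob
  expect_equal(dim(Pd), c(2L * 2L, 6L))      # (seconds x batch) rows
  expect_equal(rowSums(Pd), rep(1, 4), tolerance = 1e-6)
})

test_that("one optimizer step strictly decreases the batch loss", {
  set.seed(42)
  for (kind in c("detector", "classifier")) {
    if (kind == "detector") {
      m <- breathdetect:::init_model_params(build_detector(tiny_det_cfg()), 7L)
      X <- array(rnorm(250 * 4 * 12), c(250, 4, 12))
      y <- matrix(sample.int(6, 8, TRUE), 2, 4)
    } else {
      m <- breathdetect:::init_model_params(build_classifier(tiny_clf_cfg()), 7L)
      X <- array(rnorm(125 * 4 * 12), c(125, 4, 12))
      y <- sample.int(6, 4, TRUE)
    }
    r1 <- breathdetect:::model_loss_grad(m, X, y, training = TRUE)
    m$bn <- r1$fw$bn
    grads <- breathdetect:::model_backward(m, r1$fw, r1$dZ)
    opt <- breathdetect:::opt_init(m$params, m$config$optimizer)
    upd <- breathdetect:::opt_step(m$params, grads, opt, lr = 1e-3)
    m$params <- upd$params
    r2 <- breathdetect:::model_loss_grad(m, X, y, training = TRUE)
    expect_lt(r2$loss, r1$loss)
  }
})

test_that("training is deterministic and records per-epoch history", {
  segs <- rand_segments(12, seed = 5)
  m <- build_detector(tiny_det_cfg())
  f1 <- train_model(m, segs[1:8], segs[9:12],
                    hyper = list(epochs = 3L, batch_size = 4L), seed = 3L)
  f2 <- train_model(m, segs[1:8], segs[9:12],
                    hyper = list(epochs = 3L, batch_size = 4L), seed = 3L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_equal(nrow(f1$history), 3L)
  expect_true(all(is.finite(f1$history$train_loss)))
})

test_that("the plateau rule divides the learning rate by exactly 10", {
  segs <- rand_segments(8, seed = 6)
  m <- build_detector(tiny_det_cfg())
  # min_delta so large that no epoch ever counts as an improvement
  fit <- train_model(m, segs[1:6], segs[7:8],
                     hyper = list(epochs = 5L, batch_size = 4L, patience = 2L,
                                  min_delta = 1e9),
                     seed = 1L)
  expect_equal(fit$history$lr, 0.001 * c(1, 1, 1, 0.1, 0.1) *
                 c(1, 1, 1, 1, 1))
  expect_equal(fit$history$lr[5] / fit$history$lr[1], 0.1)
})

test_that("per-second prediction returns one normalized row per second", {
  segs <- rand_segments(10, seed = 8)
  m <- build_detector(tiny_det_cfg())
  fit <- train_model(m, segs[1:8], segs[9:10],
                     hyper = list(epochs = 2L, batch_size = 4L), seed = 2L)
  pr <- predict_segment_labels(fit, segs[[1]])
  expect_equal(length(pr$labels), 2L)   # one per second of this scale
  expect_equal(dim(pr$prob), c(2L, 6L))
  expect_equal(rowSums(pr$prob), rep(1, 2), tolerance = 1e-6)
  expect_true(all(pr$labels %in% EVENT_CLASSES))
  expect_error(predict_segment_labels(fit, matrix(0, 100, 12)), "expects")
})

test_that("random search logs every trial and returns the minimum", {
  wins <- rand_windows(16, seed = 9)
  m <- build_classifier(tiny_clf_cfg())
  rs <- random_search(list(batch_size = c(4L, 8L), lr = c(1e-3, 1e-2)),
                      budget = 3L, m, wins[1:12], wins[13:16],
                      hyper = list(epochs = 2L), seed = 4L)
  expect_equal(nrow(rs$trials), 3L)
  expect_equal(min(rs$trials$val_loss), rs$best$val_loss)
  rs2 <- random_search(list(batch_size = c(4L, 8L), lr = c(1e-3, 1e-2)),
                       budget = 3L, m, wins[1:12], wins[13:16],
                       hyper = list(epochs = 2L), seed = 4L)
  expect_identical(rs$trials, rs2$trials)
})
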