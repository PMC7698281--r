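# Seeded training loop, prediction, and random hyper-parameter search.

# Stack a list of T x 12 matrices into the engine's (T, B, C) layout,
# optionally applying per-channel standardization.
stack_inputs <- function(mats, norm = NULL) {
  Tn <- nrow(mats[[1L]]); C <- ncol(mats[[1L]]); B <- length(mats)
  X <- array(0, c(Tn, B, C))
  for (b in seq_len(B)) X[, b, ] <- mats[[b]]
  if (!is.null(norm)) {
    for (c in seq_len(C)) X[, , c] <- (X[, , c] - norm$mean[c]) / norm$sd[c]
  }
  X
}

channel_norm <- function(mats) {
  all <- do.call(rbind, mats)
  s <- apply(all, 2L, sd)
  list(mean = colMeans(all), sd = ifelse(s < 1e-12, 1, s))
}

prepare_batchset <- function(model, items, norm) {
  if (model$kind == "detector") {
    mats <- lapply(items, `[[`, "data")
    y <- vapply(items, function(s) match(s$labels, EVENT_CLASSES),
                integer(model$config$per_second_outputs))
    list(X = stack_inputs(mats, norm), y = y)   # y: (T_out, B)
  } else {
    mats <- lapply(items, `[[`, "data")
    labs <- vapply(items, `[[`, character(1), "label")
    y <- if (model$task == "binary") as.integer(labs != "normal")
         else match(labs, EVENT_CLASSES)
    list(X = stack_inputs(mats, norm), y = y)
  }
}

model_loss_grad <- function(model, X, y, training) {
  if (model$kind == "detector") {
    fw <- detector_forward(model, X, training)
    lg <- cce_loss_grad(fw$prob, as.vector(y))
    list(fw = fw, loss = lg$loss, dZ = lg$dZ)
  } else if (model$task == "binary") {
    fw <- classifier_forward(model, X, training)
    lg <- bce_loss_grad(fw$prob, y)
    # d(loss)/d(logit) for sigmoid + BCE is (p - y)/N directly
    list(fw = fw, loss = lg$loss, dZ = lg$dZ)
  } else {
    fw <- classifier_forward(model, X, training)
    lg <- cce_loss_grad(fw$prob, y)
    list(fw = fw, loss = lg$loss, dZ = lg$dZ)
  }
}

model_backward <- function(model, fw, dZ) {
  if (model$kind == "detector") detector_backward(model, fw$caches, dZ)
  else classifier_backward(model, fw$caches, dZ)
}

eval_loss <- function(model, X, y, batch_size = 32L) {
  B <- dim(X)[2L]
  tot <- 0
  starts <- seq(1L, B, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, B)
    Xb <- X[, idx, , drop = FALSE]
    yb <- if (is.matrix(y)) y[, idx, drop = FALSE] else y[idx]
    r <- model_loss_grad(model, Xb, yb, training = FALSE)
    tot <- tot + r$loss * length(idx)
  }
  tot / B
}

#' Train a model with seeded, deterministic-mode optimization
#'
#' Initializes parameters from `seed`, standardizes channels using training
#' statistics, and runs minibatch gradient descent (RMSprop for classifiers,
#' Adam for the detector) with a reduce-on-plateau learning-rate rule: when
#' the validation loss has not improved by `min_delta` for `patience` epochs
#' the learning rate is multiplied by `lr_factor` (default 0.1). Two calls
#' with identical inputs and seed produce identical histories.
#'
#' @param model An untrained `bd_model` from [build_classifier()] or
#'   [build_detector()].
#' @param train,val Lists of `labeled_segment` objects (detector) or
#'   classification windows (`list(data=, label=)`).
#' @param hyper Named overrides: `batch_size` (32), `epochs` (50), `lr`
#'   (config), `patience`, `lr_factor`, `min_delta` (1e-4), `verbose`.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return The trained `bd_model` with `$history` (per-epoch train/val loss
#'   and learning rate), `$norm`, `$seed`.
#' @export
train_model <- function(model, train, val, hyper = list(), seed = 1L) {
  if (!inherits(model, "bd_model")) stop_bd("`model` must be a bd_model")
  if (!length(train) || !length(val)) stop_bd("train and validation sets must be non-empty")
  h <- utils::modifyList(list(batch_size = 32L, epochs = 50L,
                              lr = model$config$lr,
                              patience = model$config$patience %||% 3L,
                              lr_factor = model$config$lr_factor %||% 0.1,
                              min_delta = 1e-4, verbose = FALSE), hyper)
  l2 <- model$config$l2 %||% 0
  with_seed(seed, {
    model <- init_model_params(model, seed = draw_subseeds(1L))
    norm <- channel_norm(lapply(train, `[[`, "data"))
    tr <- prepare_batchset(model, train, norm)
    va <- prepare_batchset(model, val, norm)
    opt <- opt_init(model$params, model$config$optimizer)
    lr <- h$lr
    best_val <- Inf
    wait <- 0L
    hist <- vector("list", h$epochs)
    B <- dim(tr$X)[2L]
    for (ep in seq_len(h$epochs)) {
      perm <- sample.int(B)
      starts <- seq(1L, B, by = h$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + h$batch_size - 1L, B)]
        Xb <- tr$X[, idx, , drop = FALSE]
        yb <- if (is.matrix(tr$y)) tr$y[, idx, drop = FALSE] else tr$y[idx]
        r <- model_loss_grad(model, Xb, yb, training = TRUE)
        if (!is.finite(r$loss)) {
          stop_bd("non-finite training loss at epoch %d (lr %.2g); aborting", ep, lr)
        }
        model$bn <- r$fw$bn
        grads <- model_backward(model, r$fw, r$dZ)
        upd <- opt_step(model$params, grads, opt, lr, l2 = l2)
        model$params <- upd$params
        opt <- upd$opt
        ep_loss <- ep_loss + r$loss * length(idx)
      }
      ep_loss <- ep_loss / B
      val_loss <- eval_loss(model, va$X, va$y, h$batch_size)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss,
                               val_loss = val_loss, lr = lr)
      if (h$verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                        ep, ep_loss, val_loss, lr))
      }
      if (val_loss < best_val - h$min_delta) {
        best_val <- val_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= h$patience) {
          lr <- lr * h$lr_factor
          wait <- 0L
        }
      }
    }
    model$history <- do.call(rbind, hist)
    model$norm <- norm
    model$seed <- seed
    model$trained <- TRUE
    model
  })
}

#' Predict per-second labels for one segment
#'
#' @param model A trained detector `bd_model`.
#' @param segment A `labeled_segment` or a bare `3750 x 12` matrix.
#' @return List with `labels` (character, one per second) and `prob`
#'   (`segment_s x 6` matrix; each row sums to 1).
#' @export
predict_segment_labels <- function(model, segment) {
  if (!isTRUE(model$trained)) stop_bd("model has not been trained")
  if (model$kind != "detector") stop_bd("per-second prediction requires a detector model")
  dat <- if (inherits(segment, "labeled_segment")) segment$data else segment
  if (!is.matrix(dat) || nrow(dat) != model$input_shape[1L]) {
    stop_bd("segment has %d rows; this model expects %d", NROW(dat),
            model$input_shape[1L])
  }
  X <- stack_inputs(list(dat), model$norm)
  fw <- detector_forward(model, X, training = FALSE)
  P <- fw$prob
  colnames(P) <- EVENT_CLASSES
  list(labels = EVENT_CLASSES[max.col(P, ties.method = "first")], prob = P)
}

#' Predict scores/classes for classification windows
#'
#' @param model A trained classifier `bd_model`.
#' @param windows List of windows (`list(data=, label=)`) or a single window
#'   matrix.
#' @return For a binary model, a numeric vector of event probabilities; for a
#'   multi-event model, a list with `prob` (`B x 6`) and `labels`.
#' @export
predict_windows <- function(model, windows) {
  if (!isTRUE(model$trained)) stop_bd("model has not been trained")
  if (model$kind != "classifier") stop_bd("`model` must be a classifier")
  if (is.matrix(windows)) windows <- list(list(data = windows, label = "normal"))
  X <- stack_inputs(lapply(windows, `[[`, "data"), model$norm)
  fw <- classifier_forward(model, X, training = FALSE)
  if (model$task == "binary") {
    as.vector(fw$prob)
  } else {
    P <- fw$prob
    colnames(P) <- EVENT_CLASSES
    list(prob = P, labels = EVENT_CLASSES[max.col(P, ties.method = "first")])
  }
}

#' Evaluate a detector on labeled segments
#'
#' Runs per-second prediction over `segments` and scores the concatenated
#' second-level labels with [classification_report()].
#'
#' @param model Trained detector.
#' @param segments List of `labeled_segment`.
#' @return List with `report` (an `eval_report`), `truth`, `predicted`.
#' @export
evaluate_detector <- function(model, segments) {
  preds <- lapply(segments, function(s) predict_segment_labels(model, s)$labels)
  truth <- unlist(lapply(segments, `[[`, "labels"), use.names = FALSE)
  predicted <- unlist(preds, use.names = FALSE)
  list(report = classification_report(truth, predicted),
       truth = truth, predicted = predicted)
}

#' Random hyper-parameter search
#'
#' Draws `budget` seeded-random configurations from `space` (candidate sets
#' for training hyper-parameters such as `batch_size`, `lr`, `epochs`), trains
#' each, and returns the draw minimizing the final validation loss together
#' with the full trial log.
#'
#' @param space Named list of non-empty candidate vectors.
#' @param budget Number of trials (>= 1).
#' @param model Untrained `bd_model` used for every trial.
#' @param train,val Datasets as in [train_model()].
#' @param hyper Fixed hyper-parameter overrides applied to every trial.
#' @param seed Integer seed (controls the draw sequence and trial training).
#' @return List with `best` (list of chosen values + `val_loss`), `trials`
#'   (data frame log) and `best_model`.
#' @export
random_search <- function(space, budget, model, train, val, hyper = list(),
                          seed = 1L) {
  if (budget < 1L) stop_bd("`budget` must be >= 1")
  if (!length(space) || any(lengths(space) == 0L)) {
    stop_bd("every candidate set in `space` must be non-empty")
  }
  with_seed(seed, {
    draws <- lapply(seq_len(budget), function(i) {
      lapply(space, function(v) v[[sample.int(length(v), 1L)]])
    })
    trial_seeds <- draw_subseeds(budget)
    rows <- vector("list", budget)
    models <- vector("list", budget)
    for (i in seq_len(budget)) {
      hi <- utils::modifyList(hyper, draws[[i]])
      fit <- train_model(model, train, val, hyper = hi, seed = trial_seeds[i])
      models[[i]] <- fit
      rows[[i]] <- cbind(data.frame(trial = i),
                         as.data.frame(draws[[i]]),
                         data.frame(val_loss = tail(fit$history$val_loss, 1L)))
    }
    trials <- do.call(rbind, rows)
    best_i <- which.min(trials$val_loss)
    list(best = c(draws[[best_i]], list(val_loss = trials$val_loss[best_i])),
         trials = trials, best_model = models[[best_i]])
  })
}
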