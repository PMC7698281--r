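# Model configurations and architecture builders.
#
# Two families:
#  * window classifiers (AlexNet-style): 6 x [conv -> batch norm -> ReLU ->
#    max-pool] -> flatten -> 3 x [dense -> ReLU -> dropout] -> output head
#    (sigmoid for binary, 6-way softmax for multi-event), trained with RMSprop
#    and cross-entropy;
#  * per-second detector: stem conv -> BN -> ReLU, then 4 residual blocks of 2
#    convs each (widths doubling, projection shortcuts where shape changes),
#    temporal downsampling totalling x125, closed by a time-distributed dense
#    + softmax giving one 6-class probability row per second; trained with
#    Adam and a reduce-on-plateau learning-rate rule.

#' Configuration for the window classifiers
#'
#' @param task `"binary"` (sigmoid head, binary cross-entropy, L2 = 0.1) or
#'   `"multi"` (6-way softmax head, categorical cross-entropy, L2 = 0.001).
#' @param scale `"full"` (kernel 100, filters 32/64/96/96/64/64, dense widths
#'   256/128/64) or `"desk"` (a small preset for CPU experimentation).
#' @param window_s Input window length in seconds (default 7 -> 875 steps).
#' @param conv_filters,conv_kernel,pool_size,fc_widths,l2,dropout_fc,lr
#'   Optional overrides of the preset values.
#' @param channels Number of input channels (12; reduce to mask channels).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(task = c("binary", "multi"),
                              scale = c("full", "desk"),
                              window_s = 7,
                              conv_filters = NULL, conv_kernel = NULL,
                              pool_size = 2L, fc_widths = NULL,
                              l2 = NULL, dropout_fc = 0.5, lr = 0.001,
                              channels = 12L) {
  task <- match.arg(task)
  scale <- match.arg(scale)
  if (is.null(conv_filters)) {
    conv_filters <- if (scale == "full") c(32, 64, 96, 96, 64, 64) else rep(8L, 6L)
  }
  if (is.null(conv_kernel)) conv_kernel <- if (scale == "full") 100L else 25L
  if (is.null(fc_widths)) {
    fc_widths <- if (scale == "full") c(256, 128, 64) else c(32, 16, 8)
  }
  if (is.null(l2)) l2 <- if (task == "binary") 0.1 else 0.001
  if (length(conv_filters) != 6L) stop_bd("`conv_filters` must have 6 entries")
  if (length(fc_widths) != 3L) stop_bd("`fc_widths` must have 3 entries (plus the output layer)")
  if (l2 < 0) stop_bd("`l2` must be >= 0")
  if (dropout_fc < 0 || dropout_fc >= 1) stop_bd("`dropout_fc` must be in [0, 1)")
  structure(list(task = task, scale = scale, window_s = window_s,
                 n_conv_layers = 6L, n_fc_layers = 4L,
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_size = as.integer(pool_size),
                 fc_widths = as.integer(fc_widths),
                 l2 = l2, dropout_fc = dropout_fc,
                 optimizer = "rmsprop", lr = lr,
                 loss = if (task == "binary") "bce" else "cce",
                 channels = as.integer(channels)),
            class = "classifier_config")
}

#' Configuration for the residual per-second detector
#'
#' @param scale `"full"` (stem kernel 384, base 64 filters doubling to 512;
#'   ~2e8 parameters) or `"desk"` (stem kernel 64, base 8 filters; trainable
#'   on one CPU). Both keep 4 residual blocks of 2 convs and downsample time
#'   by exactly 125 so that a 30-s segment yields 30 per-second outputs; the
#'   full preset does all downsampling inside the residual blocks (strides
#'   5,5,5,1), the desk preset moves one factor of 5 into the stem.
#' @param segment_s Segment length in seconds (input = `segment_s * 125`
#'   samples, output = `segment_s` label rows).
#' @param first_kernel,block_kernel,base_filters,stem_stride,block_strides,lr
#'   Optional overrides.
#' @param n_classes Number of output classes (6).
#' @param channels Number of input channels (12).
#' @param lr_factor,patience Reduce-on-plateau rule: divide the learning rate
#'   by `1/lr_factor` when validation loss has not improved for `patience`
#'   epochs.
#' @return A `detector_config` list.
#' @export
detector_config <- function(scale = c("full", "desk"),
                            segment_s = 30L,
                            first_kernel = NULL, block_kernel = NULL,
                            base_filters = NULL,
                            stem_stride = NULL, block_strides = NULL,
                            lr = 0.001, lr_factor = 0.1, patience = 3L,
                            n_classes = 6L, channels = 12L) {
  scale <- match.arg(scale)
  if (is.null(first_kernel)) first_kernel <- if (scale == "full") 384L else 64L
  if (is.null(block_kernel)) block_kernel <- if (scale == "full") 384L else 16L
  if (is.null(base_filters)) base_filters <- if (scale == "full") 64L else 8L
  if (is.null(stem_stride)) stem_stride <- if (scale == "full") 1L else 5L
  if (is.null(block_strides)) {
    block_strides <- if (scale == "full") c(5L, 5L, 5L, 1L) else c(5L, 5L, 1L, 1L)
  }
  if (length(block_strides) != 4L) stop_bd("`block_strides` must have 4 entries")
  total <- stem_stride * prod(block_strides)
  if (total != SAMPLE_RATE) {
    stop_bd("temporal downsampling product is %d; it must equal %d so each output row covers one second",
            total, SAMPLE_RATE)
  }
  cfg <- structure(list(scale = scale, segment_s = as.integer(segment_s),
                        per_second_outputs = as.integer(segment_s),
                        first_kernel = as.integer(first_kernel),
                        block_kernel = as.integer(block_kernel),
                        base_filters = as.integer(base_filters),
                        n_residual_blocks = 4L, convs_per_block = 2L,
                        stem_stride = as.integer(stem_stride),
                        block_strides = as.integer(block_strides),
                        optimizer = "adam", lr = lr, lr_factor = lr_factor,
                        patience = as.integer(patience), loss = "cce",
                        n_classes = as.integer(n_classes),
                        channels = as.integer(channels)),
                   class = "detector_config")
  cfg
}

# Filter width of residual block i: base * 2^(i-1), so 64 -> 128 -> 256 -> 512
# at full scale.
block_filters <- function(config) {
  config$base_filters * 2L^(seq_len(config$n_residual_blocks) - 1L)
}

#' Build a window classifier
#'
#' Instantiates the AlexNet-style 1D CNN description for a
#' [classifier_config()]: 6 convolutional layers (each followed by batch
#' normalization, ReLU and max-pooling) and 4 fully connected layers (3 hidden
#' with dropout plus the output head).
#'
#' @param config A `classifier_config`.
#' @return A `bd_model` with the layer table (`$layers`), audit counts
#'   (`$n_conv`, `$n_fc`), the analytic parameter count (`$n_params`) and
#'   untrained state.
#' @export
#' @examples
#' m <- build_classifier(classifier_config("multi", scale = "desk"))
#' m$n_conv; m$n_fc
build_classifier <- function(config) {
  if (!inherits(config, "classifier_config")) stop_bd("`config` must be a classifier_config")
  Tn <- round(config$window_s * SAMPLE_RATE)
  if (config$window_s * SAMPLE_RATE != Tn) stop_bd("window length must be an integer number of samples")
  rows <- list()
  Cin <- config$channels
  Tc <- Tn
  n_params <- 0
  for (i in seq_len(6L)) {
    Fo <- config$conv_filters[i]
    np <- config$conv_kernel * Cin * Fo + Fo + 2L * Fo  # conv + bias + BN
    rows[[length(rows) + 1L]] <-
      data.frame(name = sprintf("conv%d", i), type = "conv",
                 kernel = config$conv_kernel, stride = 1L, filters = Fo,
                 t_out = Tc, n_params = np)
    Tc <- Tc %/% config$pool_size
    if (Tc < 1L) stop_bd("window too short for 6 pooling stages")
    Cin <- Fo
    n_params <- n_params + np
  }
  n_in <- Tc * Cin
  widths <- c(config$fc_widths, if (config$task == "binary") 1L else 6L)
  for (j in seq_along(widths)) {
    np <- n_in * widths[j] + widths[j]
    rows[[length(rows) + 1L]] <-
      data.frame(name = if (j < length(widths)) sprintf("fc%d", j) else "out",
                 type = "dense", kernel = NA_integer_, stride = NA_integer_,
                 filters = widths[j], t_out = NA_integer_, n_params = np)
    n_in <- widths[j]
    n_params <- n_params + np
  }
  layers <- do.call(rbind, rows)
  structure(list(kind = "classifier", task = config$task, config = config,
                 layers = layers, n_conv = sum(layers$type == "conv"),
                 n_fc = sum(layers$type == "dense"),
                 n_params = n_params, input_shape = c(Tn, config$channels),
                 flat_features = Tn * config$channels,
                 params = NULL, bn = NULL, trained = FALSE),
            class = "bd_model")
}

#' Build the residual per-second detector
#'
#' Instantiates the detector description: stem conv (+BN+ReLU), 4 residual
#' blocks of 2 convs each with widths doubling from `base_filters` and
#' projection shortcuts where width or stride changes, cumulative temporal
#' downsampling of exactly 125, and a time-distributed dense + softmax head
#' emitting one probability row per second.
#'
#' @param config A `detector_config`.
#' @return A `bd_model` (see [build_classifier()]); `$n_params` for the full
#'   preset is ~2.0e8.
#' @export
#' @examples
#' m <- build_detector(detector_config("desk"))
#' m$layers$filters
build_detector <- function(config) {
  if (!inherits(config, "detector_config")) stop_bd("`config` must be a detector_config")
  Tn <- config$segment_s * SAMPLE_RATE
  filt <- block_filters(config)
  rows <- list()
  np_stem <- config$first_kernel * config$channels * config$base_filters +
    config$base_filters + 2L * config$base_filters
  Tc <- as.integer(ceiling(Tn / config$stem_stride))
  rows[[1L]] <- data.frame(name = "stem", type = "conv",
                           kernel = config$first_kernel,
                           stride = config$stem_stride,
                           filters = config$base_filters, t_out = Tc,
                           n_params = np_stem)
  n_params <- np_stem
  Cin <- config$base_filters
  for (i in seq_len(config$n_residual_blocks)) {
    Fo <- filt[i]; s <- config$block_strides[i]
    Tc <- as.integer(ceiling(Tc / s))
    np1 <- config$block_kernel * Cin * Fo + Fo + 2L * Fo
    np2 <- config$block_kernel * Fo * Fo + Fo + 2L * Fo
    proj <- (s != 1L) || (Cin != Fo)
    npp <- if (proj) Cin * Fo + Fo else 0L
    rows[[length(rows) + 1L]] <-
      data.frame(name = sprintf("block%d", i), type = "residual_block",
                 kernel = config$block_kernel, stride = s, filters = Fo,
                 t_out = Tc, n_params = np1 + np2 + npp)
    n_params <- n_params + np1 + np2 + npp
    Cin <- Fo
  }
  if (Tc != config$per_second_outputs) {
    stop_bd("downsampling produces %d output rows, expected %d", Tc,
            config$per_second_outputs)
  }
  np_head <- Cin * config$n_classes + config$n_classes
  rows[[length(rows) + 1L]] <-
    data.frame(name = "head", type = "dense", kernel = NA_integer_,
               stride = NA_integer_, filters = config$n_classes, t_out = Tc,
               n_params = np_head)
  n_params <- n_params + np_head
  layers <- do.call(rbind, rows)
  n_conv_trunk <- 1L + config$n_residual_blocks * config$convs_per_block
  structure(list(kind = "detector", task = "detect", config = config,
                 layers = layers, n_conv = n_conv_trunk, n_fc = 1L,
                 n_params = n_params,
                 input_shape = c(Tn, config$channels),
                 params = NULL, bn = NULL, trained = FALSE),
            class = "bd_model")
}

#' @export
print.bd_model <- function(x, ...) {
  cat(sprintf("<bd_model> %s (%s), %s parameters, %s\n", x$kind, x$task,
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

# --- parameter initialization ----------------------------------------------

init_classifier_params <- function(model) {
  cfg <- model$config
  params <- list(); bn <- list()
  Cin <- cfg$channels
  for (i in seq_len(6L)) {
    Fo <- cfg$conv_filters[i]
    cv <- init_conv(cfg$conv_kernel, Cin, Fo)
    params[[sprintf("conv%d.W", i)]] <- cv$W
    params[[sprintf("conv%d.b", i)]] <- cv$b
    bi <- init_bn(Fo)
    params[[sprintf("bn%d.gamma", i)]] <- bi$gamma
    params[[sprintf("bn%d.beta", i)]] <- bi$beta
    bn[[sprintf("bn%d", i)]] <- bi$state
    Cin <- Fo
  }
  n_in <- model$layers$t_out[6L] %/% cfg$pool_size * Cin
  widths <- c(cfg$fc_widths, if (cfg$task == "binary") 1L else 6L)
  nms <- c(sprintf("fc%d", 1:3), "out")
  for (j in seq_along(widths)) {
    dn <- init_dense(n_in, widths[j])
    params[[paste0(nms[j], ".W")]] <- dn$W
    params[[paste0(nms[j], ".b")]] <- dn$b
    n_in <- widths[j]
  }
  list(params = params, bn = bn)
}

init_detector_params <- function(model) {
  cfg <- model$config
  params <- list(); bn <- list()
  st <- init_conv(cfg$first_kernel, cfg$channels, cfg$base_filters)
  params[["stem.W"]] <- st$W; params[["stem.b"]] <- st$b
  bi <- init_bn(cfg$base_filters)
  params[["stem_bn.gamma"]] <- bi$gamma; params[["stem_bn.beta"]] <- bi$beta
  bn[["stem_bn"]] <- bi$state
  Cin <- cfg$base_filters
  filt <- block_filters(cfg)
  for (i in seq_len(cfg$n_residual_blocks)) {
    Fo <- filt[i]; s <- cfg$block_strides[i]
    c1 <- init_conv(cfg$block_kernel, Cin, Fo)
    params[[sprintf("b%d_c1.W", i)]] <- c1$W; params[[sprintf("b%d_c1.b", i)]] <- c1$b
    b1 <- init_bn(Fo)
    params[[sprintf("b%d_bn1.gamma", i)]] <- b1$gamma
    params[[sprintf("b%d_bn1.beta", i)]] <- b1$beta
    bn[[sprintf("b%d_bn1", i)]] <- b1$state
    c2 <- init_conv(cfg$block_kernel, Fo, Fo)
    params[[sprintf("b%d_c2.W", i)]] <- c2$W; params[[sprintf("b%d_c2.b", i)]] <- c2$b
    b2 <- init_bn(Fo)
    params[[sprintf("b%d_bn2.gamma", i)]] <- b2$gamma
    params[[sprintf("b%d_bn2.beta", i)]] <- b2$beta
    bn[[sprintf("b%d_bn2", i)]] <- b2$state
    if (s != 1L || Cin != Fo) {
      pj <- init_conv(1L, Cin, Fo)
      params[[sprintf("b%d_proj.W", i)]] <- pj$W
      params[[sprintf("b%d_proj.b", i)]] <- pj$b
    }
    Cin <- Fo
  }
  hd <- init_dense(Cin, cfg$n_classes)
  params[["head.W"]] <- hd$W; params[["head.b"]] <- hd$b
  list(params = params, bn = bn)
}

init_model_params <- function(model, seed) {
  with_seed(seed, {
    ini <- if (model$kind == "classifier") init_classifier_params(model)
           else init_detector_params(model)
    model$params <- ini$params
    model$bn <- ini$bn
    model
  })
}

# --- forward / backward -----------------------------------------------------

# Classifier forward. X: (T, B, C). Returns head output (probabilities),
# caches for backward, and updated BN states.
classifier_forward <- function(model, X, training = FALSE) {
  cfg <- model$config; p <- model$params; bn <- model$bn
  caches <- list()
  h <- X
  for (i in seq_len(6L)) {
    cv <- conv1d_forward(h, p[[sprintf("conv%d.W", i)]],
                         p[[sprintf("conv%d.b", i)]], 1L)
    nb <- bn_forward(cv$Y, p[[sprintf("bn%d.gamma", i)]],
                     p[[sprintf("bn%d.beta", i)]], bn[[sprintf("bn%d", i)]],
                     training)
    bn[[sprintf("bn%d", i)]] <- nb$state
    rl <- relu_forward(nb$Y)
    mp <- maxpool_forward(rl$Y, cfg$pool_size)
    caches[[i]] <- list(conv = cv$cache, bn = nb$cache, relu = rl$cache,
                        pool = mp$cache)
    h <- mp$Y
  }
  d <- dim(h)
  flat_dim <- c(d[1L], d[3L])
  h <- aperm(h, c(2L, 1L, 3L))               # (B, T, F)
  dim(h) <- c(d[2L], d[1L] * d[3L])
  fc_caches <- list()
  for (j in 1:3) {
    dn <- dense_forward(h, p[[sprintf("fc%d.W", j)]], p[[sprintf("fc%d.b", j)]])
    rl <- relu_forward(dn$Y)
    dr <- dropout_forward(rl$Y, cfg$dropout_fc, training)
    fc_caches[[j]] <- list(dense = dn$cache, relu = rl$cache, drop = dr$cache)
    h <- dr$Y
  }
  out <- dense_forward(h, p[["out.W"]], p[["out.b"]])
  z <- out$Y
  prob <- if (cfg$task == "binary") sigmoid(as.vector(z)) else softmax_rows(z)
  list(prob = prob, z = z, bn = bn,
       caches = list(conv = caches, flat_dim = flat_dim, fc = fc_caches,
                     out = out$cache))
}

# dZ is the gradient at the output logits (pre-activation).
classifier_backward <- function(model, caches, dZ) {
  p <- model$params
  grads <- list()
  if (is.vector(dZ)) dZ <- matrix(dZ, ncol = 1L)
  bo <- dense_backward(dZ, p[["out.W"]], caches$out)
  grads[["out.W"]] <- bo$dW; grads[["out.b"]] <- bo$db
  dh <- bo$dX
  for (j in 3:1) {
    cc <- caches$fc[[j]]
    dh <- dropout_backward(dh, cc$drop)
    dh <- relu_backward(dh, cc$relu)
    bd <- dense_backward(dh, p[[sprintf("fc%d.W", j)]], cc$dense)
    grads[[sprintf("fc%d.W", j)]] <- bd$dW
    grads[[sprintf("fc%d.b", j)]] <- bd$db
    dh <- bd$dX
  }
  fd <- caches$flat_dim
  B <- nrow(dh)
  dim(dh) <- c(B, fd[1L], fd[2L])
  dh <- aperm(dh, c(2L, 1L, 3L))             # (T, B, F)
  for (i in 6:1) {
    cc <- caches$conv[[i]]
    dh <- maxpool_backward(dh, cc$pool)
    dh <- relu_backward(dh, cc$relu)
    bb <- bn_backward(dh, cc$bn)
    grads[[sprintf("bn%d.gamma", i)]] <- bb$dgamma
    grads[[sprintf("bn%d.beta", i)]] <- bb$dbeta
    bc <- conv1d_backward(bb$dX, p[[sprintf("conv%d.W", i)]], cc$conv)
    grads[[sprintf("conv%d.W", i)]] <- bc$dW
    grads[[sprintf("conv%d.b", i)]] <- bc$db
    dh <- bc$dX
  }
  grads
}

# Detector forward. X: (T, B, C). Returns per-second probabilities with dim
# (T_out, B, n_classes).
detector_forward <- function(model, X, training = FALSE) {
  cfg <- model$config; p <- model$params; bn <- model$bn
  cv <- conv1d_forward(X, p[["stem.W"]], p[["stem.b"]], cfg$stem_stride)
  nb <- bn_forward(cv$Y, p[["stem_bn.gamma"]], p[["stem_bn.beta"]],
                   bn[["stem_bn"]], training)
  bn[["stem_bn"]] <- nb$state
  rl <- relu_forward(nb$Y)
  h <- rl$Y
  caches <- list(stem = list(conv = cv$cache, bn = nb$cache, relu = rl$cache))
  for (i in seq_len(cfg$n_residual_blocks)) {
    s <- cfg$block_strides[i]
    inp <- h
    c1 <- conv1d_forward(h, p[[sprintf("b%d_c1.W", i)]],
                         p[[sprintf("b%d_c1.b", i)]], s)
    n1 <- bn_forward(c1$Y, p[[sprintf("b%d_bn1.gamma", i)]],
                     p[[sprintf("b%d_bn1.beta", i)]],
                     bn[[sprintf("b%d_bn1", i)]], training)
    bn[[sprintf("b%d_bn1", i)]] <- n1$state
    r1 <- relu_forward(n1$Y)
    c2 <- conv1d_forward(r1$Y, p[[sprintf("b%d_c2.W", i)]],
                         p[[sprintf("b%d_c2.b", i)]], 1L)
    n2 <- bn_forward(c2$Y, p[[sprintf("b%d_bn2.gamma", i)]],
                     p[[sprintf("b%d_bn2.beta", i)]],
                     bn[[sprintf("b%d_bn2", i)]], training)
    bn[[sprintf("b%d_bn2", i)]] <- n2$state
    has_proj <- !is.null(p[[sprintf("b%d_proj.W", i)]])
    if (has_proj) {
      pj <- conv1d_forward(inp, p[[sprintf("b%d_proj.W", i)]],
                           p[[sprintf("b%d_proj.b", i)]], s)
      sc <- pj$Y; pj_cache <- pj$cache
    } else {
      sc <- inp; pj_cache <- NULL
    }
    sum_ <- n2$Y + sc
    ro <- relu_forward(sum_)
    caches[[sprintf("block%d", i)]] <-
      list(c1 = c1$cache, bn1 = n1$cache, r1 = r1$cache, c2 = c2$cache,
           bn2 = n2$cache, proj = pj_cache, has_proj = has_proj,
           relu_out = ro$cache)
    h <- ro$Y
  }
  d <- dim(h)
  M <- h; dim(M) <- NULL
  dim(M) <- c(d[1L] * d[2L], d[3L])
  hd <- dense_forward(M, p[["head.W"]], p[["head.b"]])
  P <- softmax_rows(hd$Y)
  caches$head <- hd$cache
  caches$out_dim <- d
  list(prob = P, bn = bn, caches = caches, out_dim = d)
}

# dZ: gradient at the head logits, (T_out*B, n_classes).
detector_backward <- function(model, caches, dZ) {
  cfg <- model$config; p <- model$params
  grads <- list()
  bh <- dense_backward(dZ, p[["head.W"]], caches$head)
  grads[["head.W"]] <- bh$dW; grads[["head.b"]] <- bh$db
  dh <- bh$dX
  dim(dh) <- caches$out_dim
  for (i in cfg$n_residual_blocks:1) {
    cc <- caches[[sprintf("block%d", i)]]
    dh <- relu_backward(dh, cc$relu_out)
    # branch gradients: main path through bn2<-c2<-relu<-bn1<-c1, shortcut
    db2 <- bn_backward(dh, cc$bn2)
    grads[[sprintf("b%d_bn2.gamma", i)]] <- db2$dgamma
    grads[[sprintf("b%d_bn2.beta", i)]] <- db2$dbeta
    bc2 <- conv1d_backward(db2$dX, p[[sprintf("b%d_c2.W", i)]], cc$c2)
    grads[[sprintf("b%d_c2.W", i)]] <- bc2$dW
    grads[[sprintf("b%d_c2.b", i)]] <- bc2$db
    dm <- relu_backward(bc2$dX, cc$r1)
    db1 <- bn_backward(dm, cc$bn1)
    grads[[sprintf("b%d_bn1.gamma", i)]] <- db1$dgamma
    grads[[sprintf("b%d_bn1.beta", i)]] <- db1$dbeta
    bc1 <- conv1d_backward(db1$dX, p[[sprintf("b%d_c1.W", i)]], cc$c1)
    grads[[sprintf("b%d_c1.W", i)]] <- bc1$dW
    grads[[sprintf("b%d_c1.b", i)]] <- bc1$db
    dmain <- bc1$dX
    if (cc$has_proj) {
      bp <- conv1d_backward(dh, p[[sprintf("b%d_proj.W", i)]], cc$proj)
      grads[[sprintf("b%d_proj.W", i)]] <- bp$dW
      grads[[sprintf("b%d_proj.b", i)]] <- bp$db
      dh <- dmain + bp$dX
    } else {
      dh <- dmain + dh
    }
  }
  dh <- relu_backward(dh, caches$stem$relu)
  bb <- bn_backward(dh, caches$stem$bn)
  grads[["stem_bn.gamma"]] <- bb$dgamma
  grads[["stem_bn.beta"]] <- bb$dbeta
  bc <- conv1d_backward(bb$dX, p[["stem.W"]], caches$stem$conv)
  grads[["stem.W"]] <- bc$dW
  grads[["stem.b"]] <- bc$db
  grads
}
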