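# Minimal 1D convolutional network engine.
#
# All activations use the tensor layout (time, batch, channel), so batch-norm
# statistics and dense heads reduce to plain matrix operations, and conv1d
# becomes an im2col gather followed by one BLAS matmul. Gradients are exact
# (hand-derived backward passes); optimizers are RMSprop and Adam with an
# optional reduce-on-plateau learning-rate schedule handled by the trainer.

conv1d_pad <- function(Tn, k, stride) {
  To <- as.integer(ceiling(Tn / stride))
  pt <- max(0L, (To - 1L) * stride + k - Tn)
  list(To = To, left = pt %/% 2L, right = pt - pt %/% 2L)
}

# X: (T, B, C); W: (k*C, F) with kernel position varying fastest within each
# input channel; b: length F. "Same" zero padding so T_out = ceiling(T/stride).
conv1d_forward <- function(X, W, b, stride, keep_cache = TRUE) {
  d <- dim(X); Tn <- d[1L]; B <- d[2L]; C <- d[3L]
  kC <- nrow(W); k <- kC %/% C; Fo <- ncol(W)
  stopifnot(k * C == kC)
  pp <- conv1d_pad(Tn, k, stride)
  if (pp$left + pp$right > 0L) {
    Xp <- array(0, c(Tn + pp$left + pp$right, B, C))
    Xp[pp$left + seq_len(Tn), , ] <- X
  } else {
    Xp <- X
  }
  Tp <- dim(Xp)[1L]
  idx <- rep((0:(pp$To - 1L)) * stride, each = k) + seq_len(k)
  Xg <- Xp[idx, , , drop = FALSE]            # (k*To, B, C)
  dim(Xg) <- c(k, pp$To, B, C)
  Xcol <- aperm(Xg, c(2L, 3L, 1L, 4L))       # (To, B, k, C)
  dim(Xcol) <- c(pp$To * B, k * C)
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = pp$To * B)
  dim(Y) <- c(pp$To, B, Fo)
  cache <- if (keep_cache) {
    list(Xcol = Xcol, idx = idx, Tp = Tp, left = pp$left, Tn = Tn,
         B = B, C = C, k = k, To = pp$To)
  }
  list(Y = Y, cache = cache)
}

conv1d_backward <- function(dY, W, cache) {
  To <- cache$To; B <- cache$B; C <- cache$C; k <- cache$k
  Fo <- ncol(W)
  dim(dY) <- c(To * B, Fo)
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)                       # (To*B, k*C)
  dim(dXcol) <- c(To, B, k, C)
  dXg <- aperm(dXcol, c(3L, 1L, 2L, 4L))     # (k, To, B, C)
  dim(dXg) <- c(k * To, B * C)
  gs <- rowsum(dXg, group = cache$idx)
  dXp <- matrix(0, cache$Tp, B * C)
  dXp[as.integer(rownames(gs)), ] <- gs
  dXp <- dXp[cache$left + seq_len(cache$Tn), , drop = FALSE]
  dim(dXp) <- c(cache$Tn, B, C)
  list(dX = dXp, dW = dW, db = db)
}

# Batch normalization over (time, batch) per channel. `state` carries running
# mean/var for inference mode.
bn_forward <- function(X, gamma, beta, state, training, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(X); N <- d[1L] * d[2L]; C <- d[3L]
  M <- X; dim(M) <- c(N, C)
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M * M) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  Xh <- (M - rep(mu, each = N)) * rep(inv, each = N)
  Y <- Xh * rep(gamma, each = N) + rep(beta, each = N)
  dim(Y) <- d
  list(Y = Y, state = state,
       cache = list(Xh = Xh, inv = inv, gamma = gamma, d = d, training = training))
}

bn_backward <- function(dY, cache) {
  d <- cache$d; N <- d[1L] * d[2L]
  dYm <- dY; dim(dYm) <- c(N, d[3L])
  Xh <- cache$Xh
  dgamma <- colSums(dYm * Xh)
  dbeta <- colSums(dYm)
  if (cache$training) {
    coef <- rep(cache$gamma * cache$inv / N, each = N)
    dX <- coef * (N * dYm - rep(dbeta, each = N) - Xh * rep(dgamma, each = N))
  } else {
    dX <- dYm * rep(cache$gamma * cache$inv, each = N)
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(Y = X * mask, cache = mask)
}

relu_backward <- function(dY, mask) dY * mask

# Non-overlapping max pooling along time; trailing samples that do not fill a
# window are dropped.
maxpool_forward <- function(X, p) {
  d <- dim(X); Tq <- d[1L] %/% p
  Xr <- X[seq_len(Tq * p), , , drop = FALSE]
  dim(Xr) <- c(p, Tq * d[2L] * d[3L])
  best <- Xr[1L, ]
  arg <- rep(1L, ncol(Xr))
  for (j in seq_len(p)[-1L]) {
    upd <- Xr[j, ] > best
    best[upd] <- Xr[j, upd]
    arg[upd] <- j
  }
  Y <- best
  dim(Y) <- c(Tq, d[2L], d[3L])
  list(Y = Y, cache = list(arg = arg, p = p, d = d, Tq = Tq))
}

maxpool_backward <- function(dY, cache) {
  d <- cache$d; Tq <- cache$Tq; p <- cache$p
  n <- Tq * d[2L] * d[3L]
  dXr <- matrix(0, p, n)
  dXr[cbind(cache$arg, seq_len(n))] <- as.vector(dY)
  dX <- array(0, d)
  dim(dXr) <- c(Tq * p, d[2L], d[3L])
  dX[seq_len(Tq * p), , ] <- dXr
  dX
}

dense_forward <- function(X, W, b) {
  list(Y = X %*% W + rep(b, each = nrow(X)), cache = X)
}

dense_backward <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  mask <- (matrix(runif(length(X)), nrow(X)) > rate) / (1 - rate)
  list(Y = X * mask, cache = mask)
}

dropout_backward <- function(dY, mask) if (is.null(mask)) dY else dY * mask

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Categorical cross-entropy over softmax probabilities P (N x K) against
# integer targets y in 1..K. Returns loss and the gradient wrt logits.
cce_loss_grad <- function(P, y) {
  N <- nrow(P)
  eps <- 1e-12
  loss <- -mean(log(pmax(P[cbind(seq_len(N), y)], eps)))
  dZ <- P
  dZ[cbind(seq_len(N), y)] <- dZ[cbind(seq_len(N), y)] - 1
  list(loss = loss, dZ = dZ / N)
}

# Binary cross-entropy over sigmoid probabilities p against 0/1 targets.
bce_loss_grad <- function(p, y) {
  eps <- 1e-12
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  list(loss = loss, dZ = (p - y) / length(y))
}

# Seeded parameter initialization (He for conv/dense feeding ReLU).
init_conv <- function(k, C, Fo) {
  list(W = matrix(rnorm(k * C * Fo) * sqrt(2 / (k * C)), k * C, Fo),
       b = rep(0, Fo))
}

init_dense <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out) * sqrt(2 / n_in), n_in, n_out),
       b = rep(0, n_out))
}

init_bn <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       state = list(mean = rep(0, C), var = rep(1, C)))
}

# --- optimizers -------------------------------------------------------------

opt_init <- function(params, kind = c("adam", "rmsprop")) {
  kind <- match.arg(kind)
  st <- lapply(params, function(p) {
    if (kind == "adam") list(m = p * 0, v = p * 0) else list(v = p * 0)
  })
  list(kind = kind, t = 0L, per_param = st)
}

# One optimizer step. `l2` adds weight decay to W matrices only (names ending
# in ".W"), matching how the classifiers regularize their kernels.
opt_step <- function(params, grads, opt, lr, l2 = 0) {
  opt$t <- opt$t + 1L
  decay_mask <- stats::setNames(grepl("\\.W$", names(params)), names(params))
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (l2 > 0 && decay_mask[[nm]]) g <- g + l2 * params[[nm]]
    s <- opt$per_param[[nm]]
    if (opt$kind == "adam") {
      s$m <- 0.9 * s$m + 0.1 * g
      s$v <- 0.999 * s$v + 0.001 * g * g
      mhat <- s$m / (1 - 0.9^opt$t)
      vhat <- s$v / (1 - 0.999^opt$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
    } else {
      s$v <- 0.9 * s$v + 0.1 * g * g
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(s$v) + 1e-8)
    }
    opt$per_param[[nm]] <- s
  }
  list(params = params, opt = opt)
}
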