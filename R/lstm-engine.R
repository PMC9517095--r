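# Small single-layer LSTM regression engine.
#
# One recurrent cell with input gate i_t, forget gate f_t, output gate o_t
# and candidate state c~_t:
#   z_t = [x_t, h_{t-1}] W + b                (z split into 4 gate blocks)
#   c_t = f_t * c_{t-1} + i_t * c~_t
#   h_t = o_t * tanh(c_t)
# followed by a linear read-out y = h_L Wy + by. Trained with full
# backpropagation through time under a mean-squared-error loss and the
# Adam optimizer, in mini-batches. All operations are matrix-level over
# the batch, so plain BLAS calls carry the cost.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform weight init; forget-gate bias starts at 1 so early
# training does not flush the cell state.
lstm_init <- function(input_dim, units, seed) {
  with_seed(seed, {
    s <- sqrt(6 / (input_dim + units + 4 * units))
    W <- matrix(runif((input_dim + units) * 4 * units, -s, s),
                input_dim + units, 4 * units)
    b <- rep(0, 4 * units)
    b[(units + 1):(2 * units)] <- 1
    so <- sqrt(6 / (units + 1))
    list(W = W, b = b, Wy = matrix(runif(units, -so, so), units, 1),
         by = 0, units = units, input_dim = input_dim)
  })
}

# xs: list of length L, each an N x D matrix (time-major mini-batch).
# Returns predictions and (optionally) the per-step cache for BPTT.
lstm_forward <- function(par, xs, keep_cache = FALSE) {
  U <- par$units
  N <- nrow(xs[[1L]])
  h <- matrix(0, N, U); cc <- matrix(0, N, U)
  cache <- if (keep_cache) vector("list", length(xs)) else NULL
  i_ix <- 1:U; f_ix <- (U + 1):(2 * U)
  o_ix <- (2 * U + 1):(3 * U); g_ix <- (3 * U + 1):(4 * U)
  for (t in seq_along(xs)) {
    z <- cbind(xs[[t]], h) %*% par$W
    z <- sweep(z, 2, par$b, "+")
    i <- .sigmoid(z[, i_ix, drop = FALSE])
    f <- .sigmoid(z[, f_ix, drop = FALSE])
    o <- .sigmoid(z[, o_ix, drop = FALSE])
    g <- tanh(z[, g_ix, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cc,
                         i = i, f = f, o = o, g = g, tc = tc)
    h <- h_new; cc <- c_new
  }
  y <- drop(h %*% par$Wy) + par$by
  list(y = y, h = h, cache = cache)
}

# Mean-squared-error gradient over one mini-batch.
lstm_backward <- function(par, xs, y_true, fw) {
  U <- par$units
  N <- nrow(xs[[1L]])
  D <- ncol(xs[[1L]])
  L <- length(xs)
  dy <- matrix(2 * (fw$y - y_true) / N, N, 1)
  gW <- matrix(0, nrow(par$W), ncol(par$W))
  gb <- rep(0, 4 * U)
  gWy <- t(fw$h) %*% dy
  gby <- sum(dy)
  dh <- dy %*% t(par$Wy)
  dc <- matrix(0, N, U)
  for (t in L:1) {
    cs <- fw$cache[[t]]
    do_ <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    df <- dc * cs$c_prev
    dg <- dc * cs$i
    dz <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                do_ * cs$o * (1 - cs$o),
                dg * (1 - cs$g^2))
    gW <- gW + t(cbind(cs$x, cs$h_prev)) %*% dz
    gb <- gb + colSums(dz)
    dprev <- dz %*% t(par$W)
    dh <- dprev[, (D + 1):(D + U), drop = FALSE]
    dc <- dc * cs$f
  }
  list(W = gW, b = gb, Wy = gWy, by = gby)
}

# Mini-batch Adam training loop with validation checkpointing: the
# weights reported are those of the epoch with the lowest validation
# mean-squared error (evaluated every `eval_every` epochs), which guards
# against overfitting the small window sets typical of one sub-watershed.
# X: N x L x D array; y: length-N vector.
lstm_train <- function(X, y, units, epochs = 50, batch_size = 32,
                       learning_rate = 0.01, seed = 1,
                       val_X = NULL, val_y = NULL, eval_every = 2) {
  N <- dim(X)[1L]; L <- dim(X)[2L]; D <- dim(X)[3L]
  par <- lstm_init(D, units, child_seed(seed, "init"))
  m <- lapply(par[c("W", "b", "Wy", "by")], function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_hist <- numeric(epochs)
  best <- list(mse = Inf, par = par, epoch = 0L)
  has_val <- !is.null(val_X) && !is.null(val_y) && length(val_y) >= 2L
  # pre-slice to time-major once
  slices <- lapply(seq_len(L), function(t)
    matrix(X[, t, ], nrow = N, ncol = D))
  with_seed(child_seed(seed, "batches"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0
      for (b0 in seq(1L, N, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, N)]
        xs <- lapply(slices, function(s) s[idx, , drop = FALSE])
        fw <- lstm_forward(par, xs, keep_cache = TRUE)
        g <- lstm_backward(par, xs, y[idx], fw)
        step <- step + 1
        for (nm in names(g)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + sum((fw$y - y[idx])^2)
      }
      loss_hist[ep] <- ep_loss / N
      if (has_val && (ep %% eval_every == 0L || ep == epochs)) {
        vmse <- mean((lstm_predict(par, val_X) - val_y)^2)
        if (vmse < best$mse) best <- list(mse = vmse, par = par, epoch = ep)
      }
    }
  })
  if (has_val && best$epoch > 0L) par <- best$par
  par$loss <- loss_hist
  par$best_epoch <- if (has_val) best$epoch else epochs
  par
}

# Predict from an N x L x D array.
lstm_predict <- function(par, X) {
  N <- dim(X)[1L]; L <- dim(X)[2L]; D <- dim(X)[3L]
  xs <- lapply(seq_len(L), function(t) matrix(X[, t, ], nrow = N, ncol = D))
  lstm_forward(par, xs)$y
}
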