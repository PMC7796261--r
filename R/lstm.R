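# Minimal batched LSTM sequence classifier: stacked LSTM layers over the
# beat waveform (one scalar input per time step), ReLU dense layers with
# inverted dropout, softmax output, cross-entropy loss, RMSprop updates.
# Everything is plain matrix algebra so training is deterministic under a
# seed and cheap at the beat lengths used here.

sigmoid <- function(z) 1 / (1 + exp(-z))

lstm_init_layer <- function(d_in, h, rng_scale = NULL) {
  r <- rng_scale %||% sqrt(6 / (d_in + 5 * h))
  W <- matrix(stats::runif((d_in + h) * 4 * h, -r, r), d_in + h, 4 * h)
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1 # forget-gate bias starts open
  list(W = W, b = b, h = h, d_in = d_in)
}

dense_init_layer <- function(d_in, d_out) {
  r <- sqrt(6 / (d_in + d_out))
  list(W = matrix(stats::runif(d_in * d_out, -r, r), d_in, d_out),
       b = rep(0, d_out))
}

# Xs: list over time of B x D input matrices. Returns hidden sequence and
# the caches needed for backpropagation through time.
lstm_layer_forward <- function(Xs, layer) {
  h <- layer$h
  B <- nrow(Xs[[1]])
  Tn <- length(Xs)
  hprev <- matrix(0, B, h)
  cprev <- matrix(0, B, h)
  cache <- vector("list", Tn)
  Hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xh <- cbind(Xs[[t]], hprev)
    z <- xh %*% layer$W
    z <- sweep(z, 2, layer$b, "+")
    i <- sigmoid(z[, 1:h, drop = FALSE])
    f <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    hh <- o * tc
    cache[[t]] <- list(xh = xh, i = i, f = f, g = g, o = o,
                       c = cc, tc = tc, cprev = cprev)
    Hs[[t]] <- hh
    hprev <- hh
    cprev <- cc
  }
  list(Hs = Hs, cache = cache)
}

# dHs: list over time of B x H gradients w.r.t. the layer outputs (may
# contain NULLs meaning zero). Returns parameter gradients and the gradient
# w.r.t. the layer inputs.
lstm_layer_backward <- function(dHs, layer, fwd) {
  h <- layer$h
  d_in <- layer$d_in
  Tn <- length(fwd$cache)
  B <- nrow(fwd$cache[[1]]$xh)
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  db <- rep(0, length(layer$b))
  dXs <- vector("list", Tn)
  dh_next <- matrix(0, B, h)
  dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(Tn))) {
    ca <- fwd$cache[[t]]
    dh <- dh_next
    if (!is.null(dHs[[t]])) dh <- dh + dHs[[t]]
    do_ <- dh * ca$tc
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    df <- dc * ca$cprev
    dg <- dc * ca$i
    dc_next <- dc * ca$f
    dz <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dW <- dW + crossprod(ca$xh, dz)
    db <- db + colSums(dz)
    dxh <- dz %*% t(layer$W)
    dXs[[t]] <- dxh[, seq_len(d_in), drop = FALSE]
    dh_next <- dxh[, d_in + seq_len(h), drop = FALSE]
  }
  list(dW = dW, db = db, dXs = dXs)
}

lstm_net_init <- function(input_dim, lstm_widths, dense_widths, n_classes) {
  layers <- list()
  d <- input_dim
  for (h in lstm_widths) {
    layers[[length(layers) + 1L]] <- c(lstm_init_layer(d, h), type = "lstm")
    d <- h
  }
  for (w in dense_widths) {
    layers[[length(layers) + 1L]] <- c(dense_init_layer(d, w), type = "dense")
    d <- w
  }
  layers[[length(layers) + 1L]] <- c(dense_init_layer(d, n_classes),
                                     type = "softmax")
  layers
}

# X: B x T matrix of beat waveforms. Returns class probabilities and, when
# training, the caches for the backward pass. The dense head reads the
# top LSTM layer's hidden states averaged over time (mean pooling), so
# every part of the beat contributes to the readout. Dropout masks
# (inverted dropout, rate `dropout`) are applied after each ReLU dense
# layer.
lstm_net_forward <- function(X, layers, dropout = 0, training = FALSE) {
  B <- nrow(X)
  Tn <- ncol(X)
  act <- lapply(seq_len(Tn), function(t) X[, t, drop = FALSE])
  caches <- vector("list", length(layers))
  vec <- NULL
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "lstm") {
      fwd <- lstm_layer_forward(act, ly)
      caches[[li]] <- fwd
      act <- fwd$Hs
      vec <- Reduce(`+`, act) / Tn
    } else {
      z <- sweep(vec %*% ly$W, 2, ly$b, "+")
      if (ly$type == "dense") {
        a <- pmax(z, 0)
        mask <- NULL
        if (training && dropout > 0) {
          mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout) /
                           (1 - dropout), nrow(a), ncol(a))
          a <- a * mask
        }
        caches[[li]] <- list(input = vec, z = z, mask = mask)
        vec <- a
      } else { # softmax
        z <- z - apply(z, 1, max)
        e <- exp(z)
        p <- e / rowSums(e)
        caches[[li]] <- list(input = vec)
        vec <- p
      }
    }
  }
  list(probs = vec, caches = caches)
}

rmsprop_update <- function(layers, grads, state, lr, decay = 0.9,
                           eps = 1e-8) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in c("W", "b")) {
      gr <- g[[paste0("d", nm)]]
      v <- state[[li]][[nm]]
      if (is.null(v)) v <- gr * 0
      v <- decay * v + (1 - decay) * gr^2
      layers[[li]][[nm]] <- layers[[li]][[nm]] - lr * gr / (sqrt(v) + eps)
      state[[li]][[nm]] <- v
    }
  }
  list(layers = layers, state = state)
}

# Exact backward pass through the whole stack: the dense tail feeds a
# gradient into the last hidden state of the top LSTM layer; deeper LSTM
# layers receive the full sequence gradient from the layer above.
lstm_stack_backward <- function(X, Y, layers, fwd) {
  B <- nrow(X)
  Tn <- ncol(X)
  probs <- fwd$probs
  loss <- -mean(log(pmax(rowSums(probs * Y), 1e-300)))
  grads <- vector("list", length(layers))
  dvec <- (probs - Y) / B
  li <- length(layers)
  # dense / softmax tail
  while (li >= 1L && layers[[li]]$type %in% c("dense", "softmax")) {
    ly <- layers[[li]]
    ca <- fwd$caches[[li]]
    dz <- dvec
    if (ly$type == "dense") {
      if (!is.null(ca$mask)) dz <- dz * ca$mask
      dz <- dz * (ca$z > 0)
    }
    grads[[li]] <- list(dW = crossprod(ca$input, dz), db = colSums(dz))
    dvec <- dz %*% t(ly$W)
    li <- li - 1L
  }
  # recurrent stack: the mean-pooled readout spreads the head gradient
  # uniformly over the top layer's time steps; deeper layers receive the
  # full sequence gradient from the layer above
  dHs <- lapply(seq_len(Tn), function(t) dvec / Tn)
  while (li >= 1L) {
    ly <- layers[[li]]
    bk <- lstm_layer_backward(dHs, ly, fwd$caches[[li]])
    grads[[li]] <- list(dW = bk$dW, db = bk$db)
    dHs <- bk$dXs
    li <- li - 1L
  }
  list(grads = grads, loss = loss)
}

train_lstm <- function(X, y_int, n_classes, lstm_widths, dense_widths,
                       dropout = 0.5, lr = 1e-3, epochs = 10,
                       batch_size = 16, seed = 1L, verbose = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  layers <- lstm_net_init(1L, lstm_widths, dense_widths, n_classes)
  state <- vector("list", length(layers))
  B <- nrow(X)
  Y <- matrix(0, B, n_classes)
  Y[cbind(seq_len(B), y_int)] <- 1
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(B)
    losses <- c()
    for (start in seq(1, B, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, B)]
      fwd <- lstm_net_forward(X[idx, , drop = FALSE], layers,
                              dropout = dropout, training = TRUE)
      bk <- lstm_stack_backward(X[idx, , drop = FALSE],
                                Y[idx, , drop = FALSE], layers, fwd)
      up <- rmsprop_update(layers, bk$grads, state, lr)
      layers <- up$layers
      state <- up$state
      losses <- c(losses, bk$loss)
    }
    loss_hist[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f", ep, epochs, loss_hist[ep]))
  }
  list(layers = layers, loss = loss_hist)
}

predict_lstm <- function(layers, X) {
  lstm_net_forward(X, layers, dropout = 0, training = FALSE)$probs
}
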