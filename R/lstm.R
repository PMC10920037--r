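# Minimal batched LSTM + linear-layer primitives with hand-derived
# backpropagation. Everything is vectorized over the batch dimension;
# sequences here are short (4 waves), so an explicit time loop is cheap.
# Gate layout in the 4H-wide weight blocks: input, forget, cell, output.

glorot_init <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

lstm_init <- function(input_size, hidden_size) {
  b <- rep(0, 4 * hidden_size)
  b[hidden_size + seq_len(hidden_size)] <- 1  # forget-gate bias at 1
  list(Wx = glorot_init(input_size, 4 * hidden_size),
       Wh = glorot_init(hidden_size, 4 * hidden_size),
       b = b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# X: n x T x D array. Returns hidden states and the cache needed for the
# backward pass. h0/c0: optional n x H initial states.
lstm_forward <- function(X, Wx, Wh, b, h0 = NULL, c0 = NULL) {
  n <- dim(X)[1]; TT <- dim(X)[2]
  H <- nrow(Wh)
  h <- if (is.null(h0)) matrix(0, n, H) else h0
  cc <- if (is.null(c0)) matrix(0, n, H) else c0
  cache <- vector("list", TT)
  Hs <- array(0, dim = c(n, TT, H))
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2 * H + i1; i4 <- 3 * H + i1
  for (t in seq_len(TT)) {
    xt <- matrix(X[, t, ], n, dim(X)[3])
    h_prev <- h
    c_prev <- cc
    A <- xt %*% Wx + h_prev %*% Wh + matrix(b, n, 4 * H, byrow = TRUE)
    ig <- sigmoid(A[, i1, drop = FALSE])
    fg <- sigmoid(A[, i2, drop = FALSE])
    gg <- tanh(A[, i3, drop = FALSE])
    og <- sigmoid(A[, i4, drop = FALSE])
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h <- og * tc
    cache[[t]] <- list(x = xt, i = ig, f = fg, g = gg, o = og,
                       c_prev = c_prev, tanh_c = tc, h_prev = h_prev)
    Hs[, t, ] <- h
  }
  list(H = Hs, h_last = h, c_last = cc, cache = cache)
}

# dH: n x T x H array of gradients w.r.t. each hidden state (zeros where
# unused). Returns parameter gradients, input gradients and gradients
# w.r.t. the initial states.
lstm_backward <- function(fw, Wx, Wh, dH) {
  cache <- fw$cache
  TT <- length(cache)
  n <- nrow(cache[[1]]$x)
  D <- ncol(cache[[1]]$x)
  H <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- rep(0, 4 * H)
  dX <- array(0, dim = c(n, TT, D))
  dh_next <- matrix(0, n, H)
  dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(TT))) {
    cc <- cache[[t]]
    dh <- matrix(dH[, t, ], n, H) + dh_next
    do_ <- dh * cc$tanh_c
    dc <- dc_next + dh * cc$o * (1 - cc$tanh_c^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dA)
    dWh <- dWh + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dX[, t, ] <- dA %*% t(Wx)
    dh_next <- dA %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX, dh0 = dh_next, dc0 = dc_next)
}

# Adam with global gradient-norm clipping. `params` and `grads` are flat
# named lists of numeric arrays; `state` is created on first use.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5,
                      weight_decay = 0, decay_skip = character(0)) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > clip)
    grads <- lapply(grads, function(g) g * (clip / gnorm))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && !(nm %in% decay_skip))
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
  }
  list(params = params, state = state)
}
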