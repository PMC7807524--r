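#' Weights of one peephole LSTM layer
#'
#' Holds the full weight set of a memory-block layer with `H` cells fed by
#' `I` inputs: input/recurrent matrices `Wx*` (H x I) and `Wh*` (H x H) for
#' the input gate (`i`), forget gate (`f`), output gate (`o`) and cell input
#' (`c`); diagonal peephole vectors `pi`, `pf`, `po` (length H) connecting
#' the cell value to the three gates; and per-gate bias vectors defaulting
#' to zero, in which case one step of the cell reproduces the bias-free
#' printed forward equations exactly. The input- and forget-gate peepholes
#' read the previous cell value, the output-gate peephole the current one.
#'
#' @param Wxi,Whi,pi,bi input-gate weights (input, recurrent, peephole, bias).
#' @param Wxf,Whf,pf,bf forget-gate weights.
#' @param Wxo,Who,po,bo output-gate weights.
#' @param Wxc,Whc,bc cell-input weights (no peephole reaches the cell input).
#' @return an object of class `lstm_cell_weights`.
#' @export
lstm_cell_weights <- function(Wxi, Whi, pi, Wxf, Whf, pf,
                              Wxo, Who, po, Wxc, Whc,
                              bi = NULL, bf = NULL, bo = NULL, bc = NULL) {
  as_m <- function(m) if (is.matrix(m)) m else matrix(m, nrow = length(m))
  Wxi <- as_m(Wxi); Wxf <- as_m(Wxf); Wxo <- as_m(Wxo); Wxc <- as_m(Wxc)
  Whi <- as_m(Whi); Whf <- as_m(Whf); Who <- as_m(Who); Whc <- as_m(Whc)
  H <- nrow(Wxi)
  zero <- rep(0, H)
  w <- list(Wxi = Wxi, Whi = Whi, pi = as.numeric(pi), bi = bi %||% zero,
            Wxf = Wxf, Whf = Whf, pf = as.numeric(pf), bf = bf %||% zero,
            Wxo = Wxo, Who = Who, po = as.numeric(po), bo = bo %||% zero,
            Wxc = Wxc, Whc = Whc, bc = bc %||% zero)
  dims_ok <-
    all(vapply(w[c("Wxf", "Wxo", "Wxc")], function(m)
      identical(dim(m), dim(Wxi)), TRUE)) &&
    all(vapply(w[c("Whi", "Whf", "Who", "Whc")], function(m)
      identical(dim(m), c(H, H)), TRUE)) &&
    all(vapply(w[c("pi", "pf", "po", "bi", "bf", "bo", "bc")], function(v)
      length(v) == H, TRUE))
  if (!dims_ok) stop_arg("inconsistent LSTM weight dimensions")
  if (!all(vapply(w, function(x) all(is.finite(x)), TRUE))) {
    stop_arg("LSTM weights must be finite")
  }
  structure(w, class = "lstm_cell_weights")
}

#' Initial (zero) LSTM state
#' @param H number of cells.
#' @return list with cell values `s`, hidden outputs `h` (both zero vectors
#'   of length H) and time index `t = 0`.
#' @export
lstm_state <- function(H) list(s = rep(0, H), h = rep(0, H), t = 0L)

#' One forward step of the peephole LSTM cell
#'
#' Reference (pure R, vectorized over cells) implementation of a single
#' memory-block step. Gate activation is the logistic sigmoid; cell input
#' and cell output pass through tanh. Order of evaluation: input gate and
#' forget gate read the previous cell value, the cell value is updated, the
#' output gate reads the updated (current) cell value, and the block output
#' is the gated tanh of the current cell value.
#'
#' @param weights an [lstm_cell_weights()].
#' @param state an [lstm_state()] (or the state returned by a previous step).
#' @param x_t numeric input vector of length `I`.
#' @return list with `state` (updated `s`, `h`, `t`) and `output`
#'   (the block output, identical to the new `h`).
#' @examples
#' w <- lstm_cell_weights(Wxi = 1, Whi = 1, pi = 1, Wxf = 1, Whf = 1, pf = 1,
#'                        Wxo = 1, Who = 1, po = 1, Wxc = 1, Whc = 1)
#' lstm_cell_step(w, lstm_state(1), 1)$output
#' @export
lstm_cell_step <- function(weights, state, x_t) {
  stopifnot(inherits(weights, "lstm_cell_weights"))
  x_t <- as.numeric(x_t)
  if (length(x_t) != ncol(weights$Wxi)) {
    stop_arg("input length ", length(x_t), " does not match I = ",
             ncol(weights$Wxi))
  }
  if (!all(is.finite(x_t))) stop_arg("non-finite input")
  s_prev <- state$s; h_prev <- state$h
  sigm <- function(a) 1 / (1 + exp(-a))

  a_i <- drop(weights$Wxi %*% x_t + weights$Whi %*% h_prev) +
    weights$pi * s_prev + weights$bi
  b_i <- sigm(a_i)
  a_f <- drop(weights$Wxf %*% x_t + weights$Whf %*% h_prev) +
    weights$pf * s_prev + weights$bf
  b_f <- sigm(a_f)
  a_c <- drop(weights$Wxc %*% x_t + weights$Whc %*% h_prev) + weights$bc
  s_new <- b_f * s_prev + b_i * tanh(a_c)
  a_o <- drop(weights$Wxo %*% x_t + weights$Who %*% h_prev) +
    weights$po * s_new + weights$bo
  b_o <- sigm(a_o)
  out <- b_o * tanh(s_new)

  list(state = list(s = s_new, h = out, t = state$t + 1L), output = out)
}

#' LSTM network architecture
#'
#' @param layers number of stacked recurrent layers.
#' @param hidden cells per layer.
#' @param dropout dropout rate applied between stacked layers during
#'   training only (inactive at inference and when `layers == 1`).
#' @param time_steps input window length W.
#' @param bias enable trainable gate biases (the forget-gate bias is
#'   initialized to 1, a standard choice that eases early gradient flow).
#' @return an object of class `lstm_config`.
#' @export
lstm_config <- function(layers = 2L, hidden = 64L, dropout = 0.20,
                        time_steps = 20L, bias = TRUE) {
  if (dropout < 0 || dropout >= 1) stop_arg("dropout must be in [0, 1)")
  if (time_steps < 1L) stop_arg("time_steps must be >= 1")
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 dropout = dropout, time_steps = as.integer(time_steps),
                 bias = isTRUE(bias)),
            class = "lstm_config")
}

#' LSTM training settings
#'
#' Minibatch Adam on mean-squared-error loss. Defaults follow the settings
#' used for the surface-signal predictor: learning rate 0.001, batch 64,
#' 60 epochs; the external/internal correlator uses 40 epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs (>= 0).
#' @param seed integer seed controlling weight initialization, batch
#'   shuffling and dropout masks.
#' @return an object of class `lstm_train_config`.
#' @export
lstm_train_config <- function(learning_rate = 0.001, batch_size = 64L,
                              epochs = 60L, seed = 0L) {
  if (learning_rate <= 0) stop_arg("learning rate must be positive")
  if (epochs < 0) stop_arg("epochs must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "lstm_train_config")
}

# ---- internal: parameter containers -----------------------------------

LAYER_PARAM_NAMES <- c("Wxi", "Whi", "pi", "bi", "Wxf", "Whf", "pf", "bf",
                       "Wxo", "Who", "po", "bo", "Wxc", "Whc", "bc")

init_lstm_network <- function(config, input_dim = 1L) {
  layers <- vector("list", config$layers)
  I <- input_dim
  H <- config$hidden
  for (l in seq_len(config$layers)) {
    k <- 1 / sqrt(H)
    rmat <- function(r, c) matrix(runif(r * c, -k, k), r, c)
    bf0 <- if (config$bias) rep(1, H) else rep(0, H)
    layers[[l]] <- list(
      Wxi = rmat(H, I), Whi = rmat(H, H), pi = runif(H, -k, k),
      bi = rep(0, H),
      Wxf = rmat(H, I), Whf = rmat(H, H), pf = runif(H, -k, k),
      bf = bf0,
      Wxo = rmat(H, I), Who = rmat(H, H), po = runif(H, -k, k),
      bo = rep(0, H),
      Wxc = rmat(H, I), Whc = rmat(H, H), bc = rep(0, H))
    I <- H
  }
  readout <- list(w = runif(H, -1 / sqrt(H), 1 / sqrt(H)), b = 0)
  structure(list(config = config, layers = layers, readout = readout,
                 input_dim = as.integer(input_dim)),
            class = "lstm_network")
}

#' @export
print.lstm_network <- function(x, ...) {
  cat(sprintf("<lstm_network> %d layer(s) x %d cells, W = %d, dropout %.0f%%\n",
              x$config$layers, x$config$hidden, x$config$time_steps,
              100 * x$config$dropout))
  invisible(x)
}

layer_forward <- function(X_cube, w) {
  .lstm_layer_forward_cpp(X_cube,
    w$Wxi, w$Whi, w$pi, w$bi, w$Wxf, w$Whf, w$pf, w$bf,
    w$Wxo, w$Who, w$po, w$bo, w$Wxc, w$Whc, w$bc,
    matrix(0, nrow(w$Whi), dim(X_cube)[2]),
    matrix(0, nrow(w$Whi), dim(X_cube)[2]))
}

layer_backward <- function(X_cube, cache, w, dH) {
  H <- nrow(w$Whi); B <- dim(X_cube)[2]
  .lstm_layer_backward_cpp(X_cube,
    cache$i, cache$f, cache$o, cache$g, cache$s, cache$h,
    w$Whi, w$Whf, w$Who, w$Whc, w$Wxi, w$Wxf, w$Wxo, w$Wxc,
    w$pi, w$pf, w$po,
    matrix(0, H, B), matrix(0, H, B), dH)
}

# windows: M x W matrix -> input cube I(=1) x M x W
windows_to_cube <- function(X) {
  arr <- array(0, dim = c(1L, nrow(X), ncol(X)))
  arr[1L, , ] <- X
  arr
}

# Full forward pass over a batch of windows; optionally applies the supplied
# dropout masks between stacked layers (training only).
network_forward <- function(net, X, masks = NULL) {
  cube <- windows_to_cube(X)
  caches <- vector("list", length(net$layers))
  inputs <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    inputs[[l]] <- cube
    caches[[l]] <- layer_forward(cube, net$layers[[l]])
    cube <- caches[[l]]$h
    if (!is.null(masks) && l < length(net$layers)) {
      cube <- cube * masks[[l]]
    }
  }
  W <- dim(cube)[3]
  hT <- matrix(cube[, , W], nrow = dim(cube)[1])
  yhat <- drop(crossprod(hT, net$readout$w)) + net$readout$b
  list(yhat = yhat, caches = caches, inputs = inputs, hT = hT)
}

# MSE loss and gradients for a batch; returns grads structured like the
# network parameters. Used by the training loop and by gradient-check tests.
network_loss_grads <- function(net, X, y, masks = NULL) {
  fw <- network_forward(net, X, masks)
  B <- length(y)
  resid <- fw$yhat - y
  loss <- mean(resid^2)
  dyhat <- 2 * resid / B
  g_readout <- list(w = drop(fw$hT %*% dyhat), b = sum(dyhat))
  dH_top <- array(0, dim = dim(fw$caches[[length(net$layers)]]$h))
  dH_top[, , dim(dH_top)[3]] <- outer(net$readout$w, dyhat)

  g_layers <- vector("list", length(net$layers))
  dH <- dH_top
  for (l in rev(seq_along(net$layers))) {
    bk <- layer_backward(fw$inputs[[l]], fw$caches[[l]], net$layers[[l]], dH)
    g_layers[[l]] <- list(Wxi = bk$dWxi, Whi = bk$dWhi, pi = drop(bk$dpi),
                          bi = drop(bk$dbi),
                          Wxf = bk$dWxf, Whf = bk$dWhf, pf = drop(bk$dpf),
                          bf = drop(bk$dbf),
                          Wxo = bk$dWxo, Who = bk$dWho, po = drop(bk$dpo),
                          bo = drop(bk$dbo),
                          Wxc = bk$dWxc, Whc = bk$dWhc, bc = drop(bk$dbc))
    if (l > 1L) {
      dH <- bk$dX
      if (!is.null(masks)) dH <- dH * masks[[l - 1L]]
    }
  }
  list(loss = loss, layers = g_layers, readout = g_readout)
}

#' Train an LSTM sequence regressor
#'
#' Stacked peephole LSTM layers with a linear readout of the final hidden
#' output, trained by minibatch Adam on mean-squared error. Dropout is
#' applied between stacked layers during training only. All randomness
#' (initialization, shuffling, dropout masks) derives from
#' `train_config$seed`, so identical calls are bit-reproducible.
#'
#' @param config an [lstm_config()].
#' @param train_config an [lstm_train_config()].
#' @param X numeric matrix of input windows (rows = examples, columns = the
#'   W time steps); `ncol(X)` must equal `config$time_steps`.
#' @param y numeric vector of targets, one per row of X.
#' @return an `lstm_network` with an added `loss_history` attribute
#'   (mean batch MSE per epoch, length `epochs`).
#' @export
train_lstm <- function(config, train_config, X, y) {
  stopifnot(inherits(config, "lstm_config"),
            inherits(train_config, "lstm_train_config"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop_arg("empty training set")
  if (length(y) != nrow(X)) stop_arg("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_arg("training data must be finite")
  }
  if (ncol(X) != config$time_steps) {
    stop_arg("window width ", ncol(X), " does not match config time_steps ",
             config$time_steps)
  }

  with_seed(train_config$seed, {
    net <- init_lstm_network(config, input_dim = 1L)
    if (train_config$epochs == 0L) {
      net$loss_history <- numeric(0)
      return_early <- TRUE
    } else {
      return_early <- FALSE
    }
    if (return_early) {
      net
    } else {
    # Adam state mirrors the parameter structure
    zeros_like <- function(p) lapply(p, function(a) a * 0)
    m_l <- lapply(net$layers, zeros_like); v_l <- m_l
    m_r <- zeros_like(net$readout); v_r <- m_r
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- train_config$learning_rate
    step <- 0L
    M <- nrow(X)
    bs <- min(train_config$batch_size, M)
    use_dropout <- config$dropout > 0 && config$layers > 1L
    H <- config$hidden

    history <- numeric(train_config$epochs)
    for (ep in seq_len(train_config$epochs)) {
      ord <- sample.int(M)
      losses <- numeric(0)
      for (b0 in seq(1L, M, by = bs)) {
        idx <- ord[b0:min(b0 + bs - 1L, M)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        masks <- NULL
        if (use_dropout) {
          keep <- 1 - config$dropout
          masks <- lapply(seq_len(config$layers - 1L), function(l) {
            array(rbinom(H * length(idx) * config$time_steps, 1L, keep) /
                    keep,
                  dim = c(H, length(idx), config$time_steps))
          })
        }
        gr <- network_loss_grads(net, Xb, yb, masks)
        losses <- c(losses, gr$loss)

        step <- step + 1L
        corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
        for (l in seq_along(net$layers)) {
          for (nm in LAYER_PARAM_NAMES) {
            g <- gr$layers[[l]][[nm]]
            m_l[[l]][[nm]] <- b1 * m_l[[l]][[nm]] + (1 - b1) * g
            v_l[[l]][[nm]] <- b2 * v_l[[l]][[nm]] + (1 - b2) * g^2
            net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] -
              lr * (m_l[[l]][[nm]] / corr1) /
                (sqrt(v_l[[l]][[nm]] / corr2) + eps)
          }
          if (!config$bias) {
            net$layers[[l]]$bi <- net$layers[[l]]$bi * 0
            net$layers[[l]]$bf <- net$layers[[l]]$bf * 0
            net$layers[[l]]$bo <- net$layers[[l]]$bo * 0
            net$layers[[l]]$bc <- net$layers[[l]]$bc * 0
          }
        }
        for (nm in c("w", "b")) {
          g <- gr$readout[[nm]]
          m_r[[nm]] <- b1 * m_r[[nm]] + (1 - b1) * g
          v_r[[nm]] <- b2 * v_r[[nm]] + (1 - b2) * g^2
          net$readout[[nm]] <- net$readout[[nm]] -
            lr * (m_r[[nm]] / corr1) / (sqrt(v_r[[nm]] / corr2) + eps)
        }
      }
      history[ep] <- mean(losses)
    }
    net$loss_history <- history
    net
    }
  })
}

#' Predict with a trained LSTM network
#'
#' Deterministic inference (dropout disabled).
#'
#' @param net an `lstm_network` from [train_lstm()].
#' @param X matrix of input windows (rows = examples).
#' @return numeric vector of predictions.
#' @export
predict_lstm <- function(net, X) {
  stopifnot(inherits(net, "lstm_network"))
  X <- as.matrix(X)
  if (ncol(X) != net$config$time_steps) {
    stop_arg("window width ", ncol(X), " does not match network time_steps ",
             net$config$time_steps)
  }
  # chunked evaluation keeps the activation cubes small
  M <- nrow(X)
  chunk <- 2048L
  if (M <= chunk) return(network_forward(net, X)$yhat)
  out <- numeric(M)
  for (b0 in seq(1L, M, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, M)
    out[idx] <- network_forward(net, X[idx, , drop = FALSE])$yhat
  }
  out
}

#' Forward pass of an LSTM network on one window
#'
#' Runs the stacked recurrent layers over a single input window and applies
#' the linear readout to the final hidden output. Equivalent to stepping
#' [lstm_cell_step()] through every layer and time step.
#'
#' @param net an `lstm_network`.
#' @param window numeric vector of length `time_steps`.
#' @return prediction scalar.
#' @export
lstm_forward <- function(net, window) {
  window <- as.numeric(window)
  if (length(window) != net$config$time_steps) {
    stop_arg("window length ", length(window), " != time_steps ",
             net$config$time_steps)
  }
  predict_lstm(net, matrix(window, nrow = 1))
}
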