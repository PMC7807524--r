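test_that("vectorized cell matches the scalar-loop forward equations", {
  set.seed(42)
  worst_cell <- 0
  worst_layer <- 0
  for (rep in 1:100) {
    I <- sample(1:4, 1); H <- sample(1:4, 1)
    w <- random_cell_weights(I, H)
    st <- lstm_state(H)
    s <- st$s; h <- st$h
    X <- matrix(rnorm(3 * I), nrow = I)
    cube <- array(X, dim = c(I, 1, 3))
    fw <- livertrack:::layer_forward(cube, w)
    for (t in 1:3) {
      r1 <- lstm_cell_step(w, st, X[, t])
      st <- r1$state
      r2 <- oracle_cell_step(w, s, h, X[, t])
      s <- r2$s; h <- r2$h
      worst_cell <- max(worst_cell, max(abs(st$s - s)), max(abs(st$h - h)))
      worst_layer <- max(worst_layer,
                         max(abs(fw$h[, 1, t] - h)),
                         max(abs(fw$s[, 1, t] - s)))
    }
  }
  expect_lt(worst_cell, 1e-10)
  expect_lt(worst_layer, 1e-10)
})

test_that("zero weights give half-open gates and zero output", {
  H <- 3
  z <- matrix(0, H, 2)
  w <- lstm_cell_weights(Wxi = z, Whi = matrix(0, H, H), pi = rep(0, H),
                         Wxf = z, Whf = matrix(0, H, H), pf = rep(0, H),
                         Wxo = z, Who = matrix(0, H, H), po = rep(0, H),
                         Wxc = z, Whc = matrix(0, H, H))
  r <- lstm_cell_step(w, lstm_state(H), c(1.3, -2))
  expect_equal(r$state$s, rep(0, H))
  expect_equal(r$output, rep(0, H))
})

test_that("all-ones scalar cell reproduces the hand-computed chain", {
  w <- lstm_cell_weights(Wxi = 1, Whi = 1, pi = 1, Wxf = 1, Whf = 1,
                         pf = 1, Wxo = 1, Who = 1, po = 1, Wxc = 1,
                         Whc = 1)
  r <- lstm_cell_step(w, lstm_state(1), 1)
  s_expected <- sigm(1) * tanh(1)
  out_expected <- sigm(1 + s_expected) * tanh(s_expected)
  expect_equal(r$state$s, s_expected, tolerance = 1e-6)
  expect_equal(r$output, out_expected, tolerance = 1e-6)
  # the input/forget pre-activations are sigma(1): peepholes see s = 0
  expect_equal(r$state$s, 0.556775, tolerance = 1e-5)
  expect_equal(r$output, 0.417551, tolerance = 1e-4)
})

test_that("output gate peepholes read the current cell value", {
  # drive the cell so s_t != s_{t-1}, then check the output gate
  # pre-activation tracks s_t while input/forget track s_{t-1}
  set.seed(9)
  w <- random_cell_weights(1, 1)
  st <- lstm_cell_step(w, lstm_state(1), 0.7)$state
  s_prev <- st$s
  r <- lstm_cell_step(w, st, -1.1)
  s_curr <- r$state$s
  expect_gt(abs(s_curr - s_prev), 1e-6)

  x <- -1.1
  a_i <- w$Wxi[1, 1] * x + w$Whi[1, 1] * st$h + w$pi * s_prev + w$bi
  a_c <- w$Wxc[1, 1] * x + w$Whc[1, 1] * st$h + w$bc
  a_f <- w$Wxf[1, 1] * x + w$Whf[1, 1] * st$h + w$pf * s_prev + w$bf
  s_manual <- sigm(a_f) * s_prev + sigm(a_i) * tanh(a_c)
  a_o_curr <- w$Wxo[1, 1] * x + w$Who[1, 1] * st$h + w$po * s_manual + w$bo
  out_curr <- sigm(a_o_curr) * tanh(s_manual)
  a_o_prev <- w$Wxo[1, 1] * x + w$Who[1, 1] * st$h + w$po * s_prev + w$bo
  out_prev <- sigm(a_o_prev) * tanh(s_manual)
  expect_equal(r$output, out_curr, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r$output, out_prev, tolerance = 1e-8)))
})

test_that("a closed forget gate decouples the cell from its past", {
  set.seed(10)
  w <- random_cell_weights(1, 1)
  w$bf <- -60  # forget-gate pre-activation driven far negative
  w$pi <- 0    # the input-gate peephole is the only other path from s
  st1 <- lstm_cell_step(w, lstm_state(1), 0.5)$state
  r_with_past <- lstm_cell_step(w, st1, 0.2)
  st1_zeroed <- st1
  st1_zeroed$s <- 0
  r_no_past <- lstm_cell_step(w, st1_zeroed, 0.2)
  expect_lt(abs(r_with_past$state$s - r_no_past$state$s), 1e-6)
})

test_that("block outputs are bounded by one", {
  set.seed(11)
  for (rep in 1:20) {
    w <- random_cell_weights(2, 3)
    st <- lstm_state(3)
    for (t in 1:10) {
      st <- lstm_cell_step(w, st, rnorm(2, sd = 5))$state
      expect_true(all(abs(st$h) <= 1))
    }
  }
})

test_that("network forward matches stepping the reference cell", {
  set.seed(12)
  cfg <- lstm_config(layers = 2, hidden = 4, dropout = 0.5,
                     time_steps = 20)
  net <- livertrack:::init_lstm_network(cfg, 1L)
  window <- rnorm(20)
  # naive loop: layer 1 cell over time, outputs feed layer 2, readout
  step_layer <- function(w, xs) {
    H <- nrow(w$Whi)
    st <- lstm_state(H)
    hs <- matrix(0, H, length(xs[[1]]) * 0 + length(xs))
    for (t in seq_along(xs)) {
      st <- lstm_cell_step(structure(w, class = "lstm_cell_weights"),
                           st, xs[[t]])$state
      hs[, t] <- st$h
    }
    hs
  }
  h1 <- step_layer(net$layers[[1]], as.list(window))
  h2 <- step_layer(net$layers[[2]], lapply(seq_len(20), function(t) h1[, t]))
  expected <- sum(net$readout$w * h2[, 20]) + net$readout$b
  expect_equal(lstm_forward(net, window), expected, tolerance = 1e-10)
  # dropout is inactive at inference: repeated calls agree exactly
  expect_identical(lstm_forward(net, window), lstm_forward(net, window))
})

test_that("zero readout on any weights predicts zero", {
  cfg <- lstm_config(layers = 1, hidden = 4, dropout = 0, time_steps = 5)
  set.seed(13)
  net <- livertrack:::init_lstm_network(cfg, 1L)
  net$readout$w <- rep(0, 4)
  net$readout$b <- 0
  expect_equal(lstm_forward(net, rnorm(5)), 0)
})

test_that("analytic gradients match finite differences", {
  cfg <- lstm_config(layers = 1, hidden = 1, dropout = 0, time_steps = 3)
  set.seed(2)
  net <- livertrack:::init_lstm_network(cfg, 1L)
  X <- matrix(rnorm(15), 5, 3); y <- rnorm(5)
  gr <- livertrack:::network_loss_grads(net, X, y)
  eps <- 1e-5
  for (nm in livertrack:::LAYER_PARAM_NAMES) {
    for (k in seq_along(net$layers[[1]][[nm]])) {
      up <- net; up$layers[[1]][[nm]][k] <- up$layers[[1]][[nm]][k] + eps
      dn <- net; dn$layers[[1]][[nm]][k] <- dn$layers[[1]][[nm]][k] - eps
      g_num <- (livertrack:::network_loss_grads(up, X, y)$loss -
                livertrack:::network_loss_grads(dn, X, y)$loss) / (2 * eps)
      g_an <- gr$layers[[1]][[nm]][k]
      expect_lt(abs(g_num - g_an) / max(1e-6, abs(g_num), abs(g_an)),
                1e-5)
    }
  }
})

test_that("training is reproducible and epochs = 0 is a no-op", {
  set.seed(3)
  X <- matrix(rnorm(300), 30, 10); y <- rnorm(30)
  cfg <- lstm_config(layers = 1, hidden = 4, dropout = 0, time_steps = 10)
  n0 <- train_lstm(cfg, lstm_train_config(epochs = 0, seed = 5), X, y)
  expect_length(n0$loss_history, 0)
  init <- livertrack:::with_seed(5L,
    livertrack:::init_lstm_network(cfg, 1L))
  expect_equal(n0$layers, init$layers)

  a <- train_lstm(cfg, lstm_train_config(epochs = 3, seed = 5), X, y)
  b <- train_lstm(cfg, lstm_train_config(epochs = 3, seed = 5), X, y)
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$layers, b$layers)

  expect_error(train_lstm(cfg, lstm_train_config(),
                          X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("training learns the identity task", {
  set.seed(3)
  X <- matrix(rnorm(2000), 200, 10); y <- X[, 10]
  cfg <- lstm_config(layers = 1, hidden = 16, dropout = 0, time_steps = 10)
  ratios <- sapply(0:4, function(sd) {
    net <- train_lstm(cfg, lstm_train_config(epochs = 30, seed = sd,
                                             batch_size = 16), X, y)
    net$loss_history[30] / net$loss_history[1]
  })
  expect_true(all(ratios < 0.1))
})
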