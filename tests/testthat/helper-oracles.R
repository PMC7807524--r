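# Independent oracles and shared fixtures for the test suite.

sigm <- function(a) 1 / (1 + exp(-a))

# Scalar-loop implementation of the printed memory-block forward equations:
# every sum is written out explicitly, independent of the package's
# vectorized cell and of the compiled layer kernel.
oracle_cell_step <- function(w, s_prev, h_prev, x) {
  H <- length(s_prev)
  a_l <- a_f <- a_c <- a_o <- numeric(H)
  b_l <- b_f <- s_new <- b_o <- out <- numeric(H)
  for (cc in seq_len(H)) {
    a_l[cc] <- sum(w$Wxi[cc, ] * x) + w$pi[cc] * s_prev[cc] +
      sum(w$Whi[cc, ] * h_prev) + w$bi[cc]
    b_l[cc] <- sigm(a_l[cc])
    a_f[cc] <- sum(w$Wxf[cc, ] * x) + w$pf[cc] * s_prev[cc] +
      sum(w$Whf[cc, ] * h_prev) + w$bf[cc]
    b_f[cc] <- sigm(a_f[cc])
    a_c[cc] <- sum(w$Wxc[cc, ] * x) + sum(w$Whc[cc, ] * h_prev) + w$bc[cc]
    s_new[cc] <- b_f[cc] * s_prev[cc] + b_l[cc] * tanh(a_c[cc])
  }
  for (cc in seq_len(H)) {
    # output gate reads the updated cell value
    a_o[cc] <- sum(w$Wxo[cc, ] * x) + w$po[cc] * s_new[cc] +
      sum(w$Who[cc, ] * h_prev) + w$bo[cc]
    b_o[cc] <- sigm(a_o[cc])
    out[cc] <- b_o[cc] * tanh(s_new[cc])
  }
  list(s = s_new, h = out)
}

random_cell_weights <- function(I, H, biases = TRUE) {
  rm_ <- function(r, c) matrix(rnorm(r * c), r, c)
  rb <- function() if (biases) rnorm(H) else rep(0, H)
  lstm_cell_weights(Wxi = rm_(H, I), Whi = rm_(H, H), pi = rnorm(H),
                    Wxf = rm_(H, I), Whf = rm_(H, H), pf = rnorm(H),
                    Wxo = rm_(H, I), Who = rm_(H, H), po = rnorm(H),
                    Wxc = rm_(H, I), Whc = rm_(H, H),
                    bi = rb(), bf = rb(), bo = rb(), bc = rb())
}

# small, fast session for unit tests (not the study conditions)
short_session <- function(seed = 1, duration_s = 60, ...) {
  simulate_session(breathing_params(duration_s = duration_s, ...),
                   correlation_params(), seed = seed)
}

# compact LSTM settings for cheap unit-test trainings
tiny_lstm_cfg <- lstm_config(layers = 1L, hidden = 8L, dropout = 0,
                             time_steps = 20L)
tiny_lstm_train <- function(epochs = 5L, seed = 0L) {
  lstm_train_config(epochs = epochs, seed = seed)
}

# ---- memoized heavy fixtures shared by the acceptance suite -----------
# The full-scale study objects (default 300 s session, trained sweeps) are
# computed once per test run and reused by every block that needs them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# study-scale model settings (see the methods vignette for the rationale)
study_lstm_cfg <- lstm_config(layers = 1L, hidden = 8L, dropout = 0)
study_svr_cfg <- svr_config(epsilon = 0.01)

default_session <- function() {
  fixture("default_session", function() {
    preprocess_session(simulate_session(breathing_params(),
                                        correlation_params(), seed = 0))
  })
}

lstm_sweep <- function() {
  fixture("lstm_sweep", function() {
    sess <- default_session()
    lapply(c(50, 150, 200, 450), function(L) {
      train_external_predictor(sess$external, "lstm", latency_ms = L,
                               lstm_cfg = study_lstm_cfg, seed = 0)
    })
  })
}

svr_sweep <- function() {
  fixture("svr_sweep", function() {
    sess <- default_session()
    lapply(c(50, 150, 200, 450), function(L) {
      train_external_predictor(sess$external, "svr", latency_ms = L,
                               svr_cfg = study_svr_cfg, svr_stride = 3L,
                               seed = 0)
    })
  })
}

default_lstm_corr <- function() {
  fixture("default_lstm_corr", function() {
    train_correlator(default_session(), "lstm", lstm_cfg = study_lstm_cfg,
                     seed = 0)
  })
}
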