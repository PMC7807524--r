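#' Convert a system latency to prediction steps
#'
#' `i = round(latency_ms * fs / 1000)` with half-sample ties rounded up. At
#' the 20 Hz sampling rate of the liver sessions, latencies of 50, 150, 200
#' and 450 ms map to i = 1, 3, 4 and 9 steps.
#'
#' @param latency_ms system latency (>= 0, milliseconds).
#' @param sampling_rate_hz sampling rate (Hz).
#' @return integer step count i.
#' @export
latency_to_steps <- function(latency_ms, sampling_rate_hz = 20) {
  if (any(latency_ms < 0)) stop_arg("latency must be >= 0")
  as.integer(floor(latency_ms * sampling_rate_hz / 1000 + 0.5))
}

#' Latency specification
#' @param latency_ms system latency (ms).
#' @param sampling_rate_hz sampling rate (Hz).
#' @return list with `latency_ms`, `sampling_rate_hz` and the derived step
#'   count `steps`.
#' @export
latency_spec <- function(latency_ms, sampling_rate_hz = 20) {
  structure(list(latency_ms = latency_ms,
                 sampling_rate_hz = sampling_rate_hz,
                 steps = latency_to_steps(latency_ms, sampling_rate_hz)),
            class = "latency_spec")
}

#' Positional uncertainty implied by a latency
#'
#' Worst-case displacement of a point moving at `speed_mm_per_s` during the
#' system latency; the conventional quality-assurance speed of 20 mm/s gives
#' 2 mm at a 100 ms latency and 8 mm at 400 ms.
#'
#' @param latency_ms latency (ms).
#' @param speed_mm_per_s assumed target speed (mm/s).
#' @return displacement (mm).
#' @export
latency_displacement_mm <- function(latency_ms, speed_mm_per_s = 20) {
  if (any(latency_ms < 0)) stop_arg("latency must be >= 0")
  speed_mm_per_s * latency_ms / 1000
}

# ---- windowed supervised datasets -------------------------------------

new_windowed_dataset <- function(inputs, targets, W, i, sampling_rate_hz) {
  structure(list(inputs = inputs, targets = targets, W = as.integer(W),
                 i = as.integer(i), axes = names(inputs),
                 sampling_rate_hz = sampling_rate_hz),
            class = "windowed_dataset")
}

#' Number of window/target pairs per axis
#' @param dataset a windowed dataset.
#' @return pair count.
#' @export
n_pairs <- function(dataset) nrow(dataset$inputs[[1]])

windows_of <- function(v, W) {
  # rows k = v[k .. k + W - 1]
  if (W == 1L) return(matrix(v, ncol = 1))
  E <- stats::embed(v, W)
  E[, W:1, drop = FALSE]
}

#' Sliding-window dataset for latency prediction
#'
#' Per axis: stride-1 windows of `W` consecutive samples paired with the
#' sample `i` steps after the window end, the supervised form of "predict
#' the surface signal at the system latency". A trace of N samples yields
#' `N - W - i + 1` pairs; window k covers samples `k .. k+W-1` and targets
#' sample `k+W-1+i`.
#'
#' @param trace a [motion_trace()].
#' @param W window length (samples).
#' @param i prediction horizon (samples, >= 0).
#' @return a `windowed_dataset` (fields `inputs`/`targets` are per-axis
#'   lists; `W`, `i` are stored).
#' @export
make_prediction_dataset <- function(trace, W = 20L, i = 1L) {
  stopifnot(inherits(trace, "motion_trace"))
  W <- as.integer(W); i <- as.integer(i)
  n <- trace_length(trace)
  if (W < 1L || i < 0L) stop_arg("need W >= 1 and i >= 0")
  if (n < W + i) {
    stop_arg("trace too short (", n, ") for W + i = ", W + i)
  }
  M <- n - W - i + 1L
  axes <- colnames(trace$values)
  inputs <- lapply(seq_along(axes), function(j) {
    windows_of(trace$values[, j], W)[seq_len(M), , drop = FALSE]
  })
  targets <- lapply(seq_along(axes), function(j) {
    trace$values[(W + i):n, j]
  })
  names(inputs) <- names(targets) <- axes
  new_windowed_dataset(inputs, targets, W, i, trace$sampling_rate_hz)
}

#' Sliding-window dataset for external/internal correlation
#'
#' Per axis: the input is the external window ending at sample t, the
#' target the internal sample at the same instant t (horizon i = 0); axes
#' are independent, each axis model sees only its own axis.
#'
#' @param paired a [paired_traces()].
#' @param W window length (samples).
#' @return a `windowed_dataset` with `i = 0`.
#' @export
make_correlation_dataset <- function(paired, W = 20L) {
  stopifnot(inherits(paired, "paired_traces"))
  W <- as.integer(W)
  n <- trace_length(paired$external)
  if (n < W) stop_arg("paired session too short for W = ", W)
  axes <- colnames(paired$external$values)
  inputs <- lapply(seq_along(axes), function(j) {
    windows_of(paired$external$values[, j], W)
  })
  targets <- lapply(seq_along(axes), function(j) {
    paired$internal$values[W:n, j]
  })
  names(inputs) <- names(targets) <- axes
  new_windowed_dataset(inputs, targets, W, 0L,
                       paired$external$sampling_rate_hz)
}

#' Chronological train/test split
#'
#' The first `floor(fraction * M)` pairs (in time order) form the training
#' set, the remainder the test set; nothing is shuffled across the
#' boundary, the standard leakage-safe convention for time series.
#'
#' @param dataset a `windowed_dataset`.
#' @param train_fraction fraction in (0, 1).
#' @return list with elements `train` and `test`, both `windowed_dataset`s.
#' @export
chronological_split <- function(dataset, train_fraction = 0.9) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_arg("train_fraction must be in (0, 1)")
  }
  M <- n_pairs(dataset)
  m <- floor(train_fraction * M)
  if (m < 1L || m >= M) stop_arg("split leaves an empty side")
  take <- function(rows) {
    new_windowed_dataset(
      lapply(dataset$inputs, function(Xm) Xm[rows, , drop = FALSE]),
      lapply(dataset$targets, function(y) y[rows]),
      dataset$W, dataset$i, dataset$sampling_rate_hz)
  }
  list(train = take(seq_len(m)), test = take((m + 1L):M))
}

# ---- per-axis model fitting -------------------------------------------

fit_axis_model <- function(kind, X, y, W, lstm_cfg, lstm_train, svr_cfg,
                           seed, svr_stride = 1L) {
  if (kind == "lstm") {
    cfg <- lstm_cfg %||% lstm_config(time_steps = W)
    cfg$time_steps <- as.integer(W)
    tc <- lstm_train %||% lstm_train_config()
    tc$seed <- as.integer(seed)
    train_lstm(cfg, tc, X, y)
  } else {
    if (svr_stride > 1L) {
      keep <- seq(1L, nrow(X), by = as.integer(svr_stride))
      X <- X[keep, , drop = FALSE]
      y <- y[keep]
    }
    fit_svr(X, y, svr_cfg %||% svr_config())
  }
}

predict_axis_model <- function(model, X) {
  if (inherits(model, "lstm_network")) predict_lstm(model, X)
  else predict_svr(model, X)
}

#' Train an external-signal predictor
#'
#' Fits one model per axis mapping a window of the (standardized) external
#' surface signal to its value i steps ahead, compensating the system
#' latency. Standardization statistics come from the training portion of
#' the trace only and are applied unchanged to the test portion; held-out
#' errors are reported in mm after destandardization.
#'
#' @param trace preprocessed external [motion_trace()] (mm).
#' @param model_kind `"lstm"` or `"svr"`.
#' @param latency_ms system latency to compensate (ms).
#' @param W window length (samples).
#' @param train_fraction chronological training fraction (default 9:1).
#' @param lstm_cfg,lstm_train optional [lstm_config()] /
#'   [lstm_train_config()] overrides (LSTM kind only).
#' @param svr_cfg optional [svr_config()] override (SVR kind only).
#' @param svr_stride train the SVR on every `svr_stride`-th window only.
#'   Adjacent 20 Hz windows overlap in all but one sample, so thinning the
#'   training set barely changes the fit while cutting its cost; the test
#'   windows are never thinned.
#' @param seed integer; per-axis training seeds are derived as
#'   `seed, seed + 1, seed + 2`.
#' @return an object of class `external_predictor` with per-axis `models`,
#'   the `stats` used, the latency bookkeeping, and `metrics` (held-out
#'   [metrics_report()] in mm).
#' @export
train_external_predictor <- function(trace,
                                     model_kind = c("lstm", "svr"),
                                     latency_ms = 450,
                                     W = 20L,
                                     train_fraction = 0.9,
                                     lstm_cfg = NULL, lstm_train = NULL,
                                     svr_cfg = NULL, svr_stride = 1L,
                                     seed = 0L) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(trace, "motion_trace"))
  fs <- trace$sampling_rate_hz
  i <- latency_to_steps(latency_ms, fs)
  n <- trace_length(trace)
  n_train <- floor(train_fraction * n)
  stats <- standardize(trace_slice(trace, 1L, n_train))$stats
  std <- standardize(trace, stats)$trace

  ds <- make_prediction_dataset(std, W, i)
  sp <- chronological_split(ds, train_fraction)

  axes <- ds$axes
  models <- list()
  y_true <- y_pred <- matrix(0, n_pairs(sp$test), length(axes),
                             dimnames = list(NULL, axes))
  for (j in seq_along(axes)) {
    models[[axes[j]]] <- fit_axis_model(
      model_kind, sp$train$inputs[[j]], sp$train$targets[[j]], W,
      lstm_cfg, lstm_train, svr_cfg, seed + j - 1L, svr_stride)
    y_pred[, j] <- std_invert(
      predict_axis_model(models[[axes[j]]], sp$test$inputs[[j]]),
      stats$mean[j], stats$sd[j])
    y_true[, j] <- std_invert(sp$test$targets[[j]],
                              stats$mean[j], stats$sd[j])
  }
  metrics <- metrics_report(y_true, y_pred,
                            context = list(model = paste0(model_kind,
                                                          "pred"),
                                           latency_ms = latency_ms,
                                           steps = i))
  structure(list(kind = model_kind, models = models, W = as.integer(W),
                 latency_ms = latency_ms, steps = i,
                 sampling_rate_hz = fs, stats = stats, metrics = metrics),
            class = "external_predictor")
}

#' Persistence baseline for latency prediction
#'
#' The no-model baseline that reports the current surface position as the
#' future position. Evaluated on the same chronological test portion as
#' [train_external_predictor()], in mm.
#'
#' @inheritParams train_external_predictor
#' @return a [metrics_report()].
#' @export
persistence_report <- function(trace, latency_ms = 450, W = 20L,
                               train_fraction = 0.9) {
  fs <- trace$sampling_rate_hz
  i <- latency_to_steps(latency_ms, fs)
  ds <- make_prediction_dataset(trace, W, i)
  sp <- chronological_split(ds, train_fraction)
  axes <- ds$axes
  y_true <- sapply(sp$test$targets, identity)
  y_pred <- sapply(sp$test$inputs, function(Xm) Xm[, ncol(Xm)])
  metrics_report(y_true, y_pred,
                 context = list(model = "persistence",
                                latency_ms = latency_ms, steps = i))
}

#' Train an external/internal correlator
#'
#' Fits one model per axis mapping a window of the external surface signal
#' ending at time t to the internal liver position at the same time t.
#' External and internal standardization statistics are computed on the
#' training portion only. With `train_fraction = 1` the whole session is
#' used for fitting and no held-out metrics are produced (the cumulative
#' update study evaluates on its own separate segment instead).
#'
#' @param paired preprocessed [paired_traces()] (mm).
#' @param model_kind `"lstm"` or `"svr"`.
#' @param W window length (samples).
#' @param train_fraction chronological training fraction, or 1 to fit on
#'   the full session.
#' @param lstm_cfg optional [lstm_config()] override.
#' @param lstm_train optional [lstm_train_config()] override; the default
#'   uses 40 epochs for the correlator.
#' @param svr_cfg optional [svr_config()] override.
#' @param svr_stride train the SVR on every `svr_stride`-th window (see
#'   [train_external_predictor()]).
#' @param seed integer; per-axis seeds `seed .. seed + 2`.
#' @return an object of class `correlator` with per-axis `models`,
#'   `stats_ext`, `stats_int`, and `metrics` (NULL when
#'   `train_fraction = 1`).
#' @export
train_correlator <- function(paired,
                             model_kind = c("lstm", "svr"),
                             W = 20L,
                             train_fraction = 0.9,
                             lstm_cfg = NULL, lstm_train = NULL,
                             svr_cfg = NULL, svr_stride = 1L,
                             seed = 0L) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(paired, "paired_traces"))
  n <- trace_length(paired$external)
  full_fit <- train_fraction >= 1
  n_train <- if (full_fit) n else floor(train_fraction * n)
  stats_ext <- standardize(trace_slice(paired$external, 1L, n_train))$stats
  stats_int <- standardize(trace_slice(paired$internal, 1L, n_train))$stats
  std_pair <- paired_traces(standardize(paired$external, stats_ext)$trace,
                            standardize(paired$internal, stats_int)$trace)

  ds <- make_correlation_dataset(std_pair, W)
  if (full_fit) {
    train <- ds
    test <- NULL
  } else {
    sp <- chronological_split(ds, train_fraction)
    train <- sp$train
    test <- sp$test
  }

  lstm_train <- lstm_train %||% lstm_train_config(epochs = 40L)
  axes <- ds$axes
  models <- list()
  for (j in seq_along(axes)) {
    models[[axes[j]]] <- fit_axis_model(
      model_kind, train$inputs[[j]], train$targets[[j]], W,
      lstm_cfg, lstm_train, svr_cfg, seed + j - 1L, svr_stride)
  }
  corr <- structure(list(kind = model_kind, models = models,
                         W = as.integer(W),
                         sampling_rate_hz = paired$external$sampling_rate_hz,
                         stats_ext = stats_ext, stats_int = stats_int,
                         metrics = NULL),
                    class = "correlator")
  if (!is.null(test)) {
    axes_n <- length(axes)
    y_true <- y_pred <- matrix(0, n_pairs(test), axes_n,
                               dimnames = list(NULL, axes))
    for (j in seq_len(axes_n)) {
      y_pred[, j] <- std_invert(predict_axis_model(models[[j]],
                                                   test$inputs[[j]]),
                                stats_int$mean[j], stats_int$sd[j])
      y_true[, j] <- std_invert(test$targets[[j]],
                                stats_int$mean[j], stats_int$sd[j])
    }
    corr$metrics <- metrics_report(
      y_true, y_pred,
      context = list(model = paste0(model_kind, "corr")))
  }
  corr
}

#' Evaluate a correlator on a separate paired segment
#'
#' Applies the correlator (with its stored training-set standardization
#' statistics) to every window of the supplied session and reports errors
#' in mm against the true internal trace.
#'
#' @param corr a `correlator` from [train_correlator()].
#' @param paired a [paired_traces()] test segment (mm).
#' @return a [metrics_report()].
#' @export
evaluate_correlator <- function(corr, paired) {
  stopifnot(inherits(corr, "correlator"), inherits(paired, "paired_traces"))
  n <- trace_length(paired$external)
  W <- corr$W
  if (n < W) stop_arg("test segment shorter than the window")
  std_ext <- standardize(paired$external, corr$stats_ext)$trace
  axes <- colnames(std_ext$values)
  y_true <- paired$internal$values[W:n, , drop = FALSE]
  y_pred <- matrix(0, n - W + 1L, length(axes),
                   dimnames = list(NULL, axes))
  for (j in seq_along(axes)) {
    Xw <- windows_of(std_ext$values[, j], W)
    y_pred[, j] <- std_invert(predict_axis_model(corr$models[[j]], Xw),
                              corr$stats_int$mean[j], corr$stats_int$sd[j])
  }
  metrics_report(y_true, y_pred,
                 context = list(model = paste0(corr$kind, "corr"),
                                evaluation = "held-out segment"))
}

# ---- integrated latency-compensated tracker ---------------------------

#' Combine a predictor and a correlator into an integrated tracker
#'
#' The integrated tracker predicts the internal liver position at time
#' t + i from external history up to t: the external predictor fills in the
#' i not-yet-observed surface samples, and the correlator maps the window
#' ending at t + i (observed values where available, predicted values for
#' the final i entries) to the internal position.
#'
#' @param predictor an `external_predictor`.
#' @param correlator a `correlator`. Both must come from the same session
#'   and preprocessing.
#' @return an object of class `integrated_tracker`.
#' @export
integrated_tracker <- function(predictor, correlator) {
  stopifnot(inherits(predictor, "external_predictor"),
            inherits(correlator, "correlator"))
  if (abs(predictor$sampling_rate_hz - correlator$sampling_rate_hz) > 1e-9) {
    stop_arg("predictor and correlator sampling rates differ")
  }
  structure(list(predictor = predictor, correlator = correlator,
                 latency_ms = predictor$latency_ms,
                 steps = predictor$steps),
            class = "integrated_tracker")
}

#' Predict the internal position ahead of real time
#'
#' One-shot prediction of the internal position at `t + i` from the most
#' recent external history ending at t. Needs at least `W + i` samples of
#' history per axis (W for the oldest predictor window, i for the horizon).
#' At i = 0 this reduces exactly to the correlator alone.
#'
#' @param tracker an [integrated_tracker()].
#' @param external_history numeric matrix (rows = samples, columns x, y, z)
#'   of external positions in mm, most recent last.
#' @return named numeric vector (x, y, z): predicted internal position (mm)
#'   at `t + i`.
#' @export
predict_internal <- function(tracker, external_history) {
  stopifnot(inherits(tracker, "integrated_tracker"))
  H <- as.matrix(external_history)
  pr <- tracker$predictor; co <- tracker$correlator
  i <- pr$steps; W_p <- pr$W; W_c <- co$W
  need <- max(W_p + i, W_c)
  if (nrow(H) < need) {
    stop_arg("need at least ", need, " history samples, got ", nrow(H))
  }
  T_ <- nrow(H)
  axes <- colnames(co$stats_ext$mean) %||% c("x", "y", "z")
  out <- numeric(3)
  for (j in seq_len(3)) {
    h <- H[, j]
    if (i > 0L) {
      hp <- std_apply(h, pr$stats$mean[j], pr$stats$sd[j])
      Xp <- t(sapply(seq_len(i), function(k) {
        hp[(T_ + k - i - W_p + 1L):(T_ + k - i)]
      }))
      if (i == 1L) Xp <- matrix(Xp, nrow = 1)
      shat_mm <- std_invert(predict_axis_model(pr$models[[j]], Xp),
                            pr$stats$mean[j], pr$stats$sd[j])
      series_mm <- c(h, shat_mm)
    } else {
      series_mm <- h
    }
    win_mm <- tail(series_mm, W_c)
    win <- std_apply(win_mm, co$stats_ext$mean[j], co$stats_ext$sd[j])
    z <- predict_axis_model(co$models[[j]], matrix(win, nrow = 1))
    out[j] <- std_invert(z, co$stats_int$mean[j], co$stats_int$sd[j])
  }
  names(out) <- c("x", "y", "z")
  out
}

#' Run the integrated tracker over a recorded session
#'
#' Replays a paired session and, for every feasible target instant, predicts
#' the internal position i steps ahead of the external history, then scores
#' the predictions against the recorded internal trace. With
#' `oracle_future = TRUE` the true future external samples are injected in
#' place of the predictor output (the perfect-predictor limit, in which the
#' integrated error equals the correlator error).
#'
#' @param tracker an [integrated_tracker()].
#' @param paired a [paired_traces()] session (mm).
#' @param eval_range optional `c(lo, hi)` restricting the evaluated target
#'   sample indices (1-based, on the session grid).
#' @param oracle_future logical; inject true future externals.
#' @return list with `metrics` (a [metrics_report()]), `target_index`
#'   (evaluated sample indices) and `predicted` (matrix of predicted
#'   internal positions, mm).
#' @export
track_session <- function(tracker, paired, eval_range = NULL,
                          oracle_future = FALSE) {
  stopifnot(inherits(tracker, "integrated_tracker"),
            inherits(paired, "paired_traces"))
  pr <- tracker$predictor; co <- tracker$correlator
  i <- pr$steps; W_p <- pr$W; W_c <- co$W
  n <- trace_length(paired$external)
  # all correlator-window entries after the observation horizon must be
  # predictable, i.e. their predictor windows must fit inside the session
  u0 <- max(W_c, W_c + 2L * i - 1L, W_p + 2L * i - 1L, W_p + i)
  u_hi <- n
  if (!is.null(eval_range)) {
    u0 <- max(u0, eval_range[1])
    u_hi <- min(u_hi, eval_range[2])
  }
  if (u0 > u_hi) stop_arg("no evaluable samples in the requested range")
  u <- u0:u_hi
  axes <- colnames(paired$external$values)
  predicted <- matrix(0, length(u), length(axes),
                      dimnames = list(NULL, axes))
  for (j in seq_along(axes)) {
    E <- paired$external$values[, j]
    if (i > 0L) {
      if (oracle_future) {
        phat_mm <- E
      } else {
        ep <- std_apply(E, pr$stats$mean[j], pr$stats$sd[j])
        # only indices v in [u0 - i + 1, u_hi] ever enter a correlator
        # window; their predictor windows end at v - i
        e_lo <- max(W_p, u0 - 2L * i + 1L)
        e_hi <- u_hi - i
        Xp <- windows_of(ep, W_p)[(e_lo - W_p + 1L):(e_hi - W_p + 1L), ,
                                  drop = FALSE]
        pred_std <- predict_axis_model(pr$models[[j]], Xp)
        phat_mm <- rep(NA_real_, n)
        # window ending at e predicts index e + i
        phat_mm[(e_lo + i):(e_hi + i)] <- std_invert(
          pred_std, pr$stats$mean[j], pr$stats$sd[j])
      }
    }
    obs_c <- std_apply(E, co$stats_ext$mean[j], co$stats_ext$sd[j])
    A_obs <- windows_of(obs_c, W_c)                # row r: window ending
    rows <- u - W_c + 1L                           #   at r + W_c - 1
    if (i == 0L) {
      combined <- A_obs[rows, , drop = FALSE]
    } else {
      prd_c <- std_apply(phat_mm, co$stats_ext$mean[j], co$stats_ext$sd[j])
      A_prd <- windows_of(prd_c, W_c)
      n_obs_cols <- max(W_c - i, 0L)
      combined <- cbind(
        A_obs[rows, seq_len(n_obs_cols), drop = FALSE],
        A_prd[rows, (n_obs_cols + 1L):W_c, drop = FALSE])
    }
    z <- predict_axis_model(co$models[[j]], combined)
    predicted[, j] <- std_invert(z, co$stats_int$mean[j],
                                 co$stats_int$sd[j])
  }
  truth <- paired$internal$values[u, , drop = FALSE]
  metrics <- metrics_report(truth, predicted,
                            context = list(model = "integrated",
                                           kind = pr$kind,
                                           latency_ms = pr$latency_ms,
                                           steps = i,
                                           oracle_future = oracle_future))
  list(metrics = metrics, target_index = u, predicted = predicted)
}
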