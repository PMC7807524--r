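test_that("latency-to-step conversion reproduces the 20 Hz mapping", {
  expect_equal(latency_to_steps(c(50, 150, 200, 450), 20), c(1L, 3L, 4L, 9L))
  expect_equal(latency_to_steps(0, 37), 0L)
  expect_equal(latency_to_steps(125, 20), 3L)  # half-sample ties round up
  expect_error(latency_to_steps(-1, 20), "latency")
  spec <- latency_spec(450, 20)
  expect_equal(spec$steps, 9L)
})

test_that("latency displacement follows the 20 mm/s convention", {
  expect_equal(latency_displacement_mm(100), 2)
  expect_equal(latency_displacement_mm(400), 8)
  expect_equal(latency_displacement_mm(450), 9)
})

test_that("prediction dataset indexing is exact", {
  tr <- motion_trace(cbind(x = 0:9, y = 10 * (0:9), z = 0:9 + 0.5), 1)
  ds <- make_prediction_dataset(tr, W = 3, i = 2)
  expect_equal(n_pairs(ds), 6L)
  expect_equal(ds$inputs$x[1, ], c(0, 1, 2))
  expect_equal(ds$targets$x[1], 4)
  expect_equal(ds$inputs$x[6, ], c(5, 6, 7))
  expect_equal(ds$targets$x[6], 9)
  # per-axis reconstruction is bit-exact for every pair
  for (ax in c("x", "y", "z")) {
    v <- tr$values[, ax]
    for (k in seq_len(n_pairs(ds))) {
      expect_identical(ds$inputs[[ax]][k, ], v[k:(k + 2)])
      expect_identical(ds$targets[[ax]][k], v[k + 2 + 2])
    }
  }

  # degenerate horizon: target is the window's final sample
  ds0 <- make_prediction_dataset(tr, W = 3, i = 0)
  expect_equal(n_pairs(ds0), 8L)
  expect_equal(ds0$targets$x, ds0$inputs$x[, 3])

  # exact-boundary trace yields a single pair
  ds1 <- make_prediction_dataset(trace_slice(tr, 1, 5), W = 3, i = 2)
  expect_equal(n_pairs(ds1), 1L)
  expect_error(make_prediction_dataset(trace_slice(tr, 1, 4), W = 3, i = 2),
               "short")
})

test_that("correlation dataset pairs external windows with internal now", {
  n <- 100
  ext <- motion_trace(cbind(x = 1:n, y = 1000 + 1:n, z = -(1:n)), 20)
  int <- motion_trace(cbind(x = 1:n + 0.5, y = 2 * (1:n) - 1,
                            z = rep(1, n)), 20)
  ds <- make_correlation_dataset(paired_traces(ext, int), W = 20)
  expect_equal(n_pairs(ds), 81L)
  expect_equal(ds$i, 0L)
  expect_equal(ds$targets$x, ext$values[20:n, "x"] + 0.5)
  # axes are independent: the x dataset only contains x samples
  expect_true(all(ds$inputs$x %in% ext$values[, "x"]))
  expect_false(any(ds$inputs$x %in% ext$values[, "y"]))

  # identity coupling with W = 1: target equals the window content
  ds1 <- make_correlation_dataset(paired_traces(ext, ext), W = 1)
  expect_equal(ds1$targets$y, drop(ds1$inputs$y))
})

test_that("chronological split keeps order and the 9:1 ratio", {
  tr <- motion_trace(cbind(x = 1:121, y = 1:121, z = 1:121), 1)
  ds <- make_prediction_dataset(tr, W = 20, i = 2)  # 100 pairs
  expect_equal(n_pairs(ds), 100L)
  sp <- chronological_split(ds, 0.9)
  expect_equal(n_pairs(sp$train), 90L)
  expect_equal(n_pairs(sp$test), 10L)
  # every training window precedes every test window in time
  expect_lt(max(sp$train$inputs$x[, 20]), min(sp$test$inputs$x[, 20]))

  sp2 <- chronological_split(ds, 0.5)
  expect_equal(n_pairs(sp2$train), 50L)
  expect_error(chronological_split(ds, 1.2), "fraction")
})

test_that("predictor standardization depends on the training slice only", {
  sess <- short_session(seed = 5, duration_s = 60)
  pred <- train_external_predictor(sess$external, "svr", latency_ms = 50,
                                   train_fraction = 0.9)
  n_train <- floor(0.9 * trace_length(sess$external))
  train_slice <- trace_slice(sess$external, 1, n_train)
  expect_equal(pred$stats$mean, unname(colMeans(train_slice$values)))
  expect_equal(pred$stats$sd, unname(apply(train_slice$values, 2, sd)))
})

test_that("a static correlator degrades under gain drift", {
  sess <- simulate_session(
    breathing_params(duration_s = 90, noise_sd_mm = 0.02),
    correlation_params(gain_drift_per_min = 0.2,
                       internal_noise_sd_mm = 0.02),
    seed = 6)
  corr <- train_correlator(sess, "svr", train_fraction = 0.9,
                           svr_cfg = svr_config(epsilon = 0.01))
  n <- trace_length(sess$external)
  # first tenth lies inside the training period, the final tenth beyond it
  early <- evaluate_correlator(corr, paired_slice(sess, 1, floor(n / 10)))
  late <- evaluate_correlator(corr, paired_slice(sess, n - floor(n / 10), n))
  expect_gt(mean(late$rmse), mean(early$rmse))
})

test_that("integrated tracker at i = 0 reduces to the correlator", {
  sess <- short_session(seed = 7, duration_s = 60)
  corr <- train_correlator(sess, "svr", svr_cfg = svr_config(epsilon = 0.01))
  pred0 <- train_external_predictor(sess$external, "lstm", latency_ms = 0,
                                    lstm_cfg = tiny_lstm_cfg,
                                    lstm_train = tiny_lstm_train(2))
  trk <- integrated_tracker(pred0, corr)
  res <- track_session(trk, sess)
  direct <- evaluate_correlator(corr, sess)
  expect_equal(res$metrics$rmse, direct$rmse, tolerance = 1e-12)

  # the one-shot interface agrees with the batch replay
  u <- res$target_index[5]
  one <- predict_internal(trk, sess$external$values[1:u, ])
  expect_equal(unname(one), unname(res$predicted[5, ]), tolerance = 1e-10)
})

test_that("a perfect predictor makes integrated error equal correlator error", {
  sess <- short_session(seed = 8, duration_s = 60)
  corr <- train_correlator(sess, "svr", svr_cfg = svr_config(epsilon = 0.01))
  pred <- train_external_predictor(sess$external, "lstm", latency_ms = 450,
                                   lstm_cfg = tiny_lstm_cfg,
                                   lstm_train = tiny_lstm_train(2))
  trk <- integrated_tracker(pred, corr)
  res <- track_session(trk, sess, oracle_future = TRUE)
  direct <- evaluate_correlator(
    corr, paired_slice(sess, res$target_index[1] - corr$W + 1,
                       trace_length(sess$external)))
  expect_equal(res$metrics$rmse, direct$rmse, tolerance = 1e-12)
})

test_that("predict_internal validates its history length", {
  sess <- short_session(seed = 9, duration_s = 60)
  corr <- train_correlator(sess, "svr")
  pred <- train_external_predictor(sess$external, "lstm", latency_ms = 450,
                                   lstm_cfg = tiny_lstm_cfg,
                                   lstm_train = tiny_lstm_train(1))
  trk <- integrated_tracker(pred, corr)
  expect_error(predict_internal(trk, sess$external$values[1:10, ]),
               "history")
})
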