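test_that("generator is seed-deterministic and seed-sensitive", {
  p <- breathing_params(duration_s = 30)
  a <- simulate_external(p, seed = 7)
  b <- simulate_external(p, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(simulate_external(p, seed = 8)$values, a$values))

  s1 <- simulate_session(p, correlation_params(), seed = 3)
  s2 <- simulate_session(p, correlation_params(), seed = 3)
  expect_identical(s1$internal$values, s2$internal$values)
})

test_that("noise/jitter-free generator is periodic at the set rate", {
  p <- breathing_params(duration_s = 120, noise_sd_mm = 0,
                        period_jitter_sd = 0, amplitude_jitter_sd = 0,
                        baseline_drift_mm_per_min = 0)
  tr <- simulate_external(p, seed = 1)
  v <- tr$values[, "y"]
  n <- length(v)
  sp <- abs(fft(v - mean(v)))[2:(n %/% 2)]
  f_peak <- which.max(sp) / (n / tr$sampling_rate_hz)
  expect_lt(abs(f_peak - 1 / p$mean_period_s), 1 / (n / 20) + 1e-9)
})

test_that("zero-amplitude axis stays at zero without noise or drift", {
  p <- breathing_params(duration_s = 30, noise_sd_mm = 0,
                        baseline_drift_mm_per_min = 0,
                        amplitude_mm = c(0, 8, 4))
  tr <- simulate_external(p, seed = 2)
  expect_equal(max(abs(tr$values[, "x"])), 0)
  expect_gt(max(abs(tr$values[, "y"])), 1)
})

test_that("internal derivation applies the configured coupling", {
  p <- breathing_params(duration_s = 30, noise_sd_mm = 0)
  ext <- simulate_external(p, seed = 5)

  ident <- correlation_params(gain = 1, gain_drift_per_min = 0, lag_s = 0,
                              offset_mm = 0, internal_noise_sd_mm = 0)
  expect_equal(derive_internal(ext, ident, 1)$values, ext$values)

  const <- motion_trace(matrix(2, nrow = 100, ncol = 3), 20)
  aff <- correlation_params(gain = 0.5, gain_drift_per_min = 0, lag_s = 0,
                            offset_mm = 1, internal_noise_sd_mm = 0)
  expect_equal(unique(as.vector(derive_internal(const, aff, 1)$values)), 2)

  # deterministic coupling ignores the seed when noise is off
  cp <- correlation_params(gain_drift_per_min = 0,
                           internal_noise_sd_mm = 0)
  expect_identical(derive_internal(ext, cp, 1)$values,
                   derive_internal(ext, cp, 99)$values)
})

test_that("lag-aligned external and internal correlate perfectly", {
  p <- breathing_params(duration_s = 60, noise_sd_mm = 0)
  cp <- correlation_params(gain = 0.8, gain_drift_per_min = 0,
                           lag_s = 0.15, offset_mm = 1,
                           internal_noise_sd_mm = 0)
  sess <- simulate_session(p, cp, seed = 4)
  tt <- trace_times(sess$external)
  e_lag <- approx(tt, sess$external$values[, "y"], xout = tt - 0.15,
                  rule = 2)$y
  expect_gt(cor(e_lag, sess$internal$values[, "y"]), 1 - 1e-9)
})

test_that("session dimensions follow duration and sampling rate", {
  sess <- simulate_session(breathing_params(duration_s = 300,
                                            sampling_rate_hz = 20),
                           correlation_params(), seed = 1)
  expect_equal(trace_length(sess$external), 6000L)
  expect_equal(trace_length(sess$internal), 6000L)
  expect_equal(sess$external$sampling_rate_hz, 20)
})

test_that("written sessions round-trip through CSV and YAML", {
  dir <- withr::local_tempdir()
  write_session(breathing_params(duration_s = 10), correlation_params(),
                seed = 6, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("external.csv",
                                               "internal.csv",
                                               "truth.yaml")))))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, 6)
  ext <- read_trace_csv(file.path(dir, "external.csv"))
  expect_equal(trace_length(ext), 200L)
})
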