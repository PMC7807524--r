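test_that("trace CSV round trip preserves values and sampling rate", {
  tr <- motion_trace(cbind(x = sin(1:50 / 5), y = cos(1:50 / 5),
                           z = (1:50) / 50), sampling_rate_hz = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  lines <- readLines(path)
  expect_length(lines, 51L)  # header + one row per sample
  expect_identical(lines[1], "time_s,x_mm,y_mm,z_mm")
  back <- read_trace_csv(path)
  expect_lt(max(abs(back$values - tr$values)), 1e-9)
  expect_equal(back$sampling_rate_hz, 20, tolerance = 1e-9)
})

test_that("trace CSV reader infers the rate and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,x_mm,y_mm,z_mm",
               "0,1,2,3", "0.05,1,2,3", "0.10,1,2,3", "0.15,1,2,3"), path)
  expect_equal(read_trace_csv(path)$sampling_rate_hz, 20)

  writeLines(c("time_s,x_mm,y_mm,z_mm",
               "0.10,1,2,3", "0,1,2,3", "0.05,1,2,3"), path)
  expect_error(read_trace_csv(path), "increasing")

  writeLines(c("time_s,x_mm", "0,1", "0.05,1"), path)
  expect_error(read_trace_csv(path), "columns")
})

test_that("resampling interpolates linearly and preserves endpoints", {
  tr <- motion_trace(matrix(c(0, 2), ncol = 1), sampling_rate_hz = 1)
  expect_equal(drop(resample_to_length(tr, 3)$values), c(0, 1, 2))

  ramp <- motion_trace(matrix(0:4, ncol = 1), sampling_rate_hz = 1)
  expect_equal(drop(resample_to_length(ramp, 3)$values), c(0, 2, 4))
  expect_equal(resample_to_length(ramp, 5)$values, ramp$values)
  expect_error(resample_to_length(ramp, 1), "target_length")
})

test_that("Hampel outlier replacement fixes spikes and nothing else", {
  const <- motion_trace(matrix(rep(5, 9), ncol = 1), 20)
  expect_equal(remove_outliers(const, 5)$values, const$values)

  spiky <- motion_trace(matrix(c(0, 0, 100, 0, 0, 0, 0), ncol = 1), 20)
  expect_equal(drop(remove_outliers(spiky, 5, 3)$values), rep(0, 7))

  tt <- seq(0, 10, by = 0.05)
  sine <- motion_trace(matrix(sin(2 * pi * tt / 4), ncol = 1), 20)
  expect_equal(remove_outliers(sine, 7, 10)$values, sine$values)
})

test_that("Hampel replacement is idempotent once spikes are removed", {
  v <- sin(seq(0, 20, by = 0.05))
  v[c(40, 100, 300)] <- c(8, -6, 10)
  tr <- motion_trace(matrix(v, ncol = 1), 20)
  once <- remove_outliers(tr, 7, 3)
  twice <- remove_outliers(once, 7, 3)
  expect_equal(twice$values, once$values)
})

test_that("smoothing/filtering has unit DC gain and kills high frequencies", {
  const <- motion_trace(matrix(rep(2.5, 200), ncol = 1), 20)
  out <- smooth_and_filter(const, 5, 2)
  expect_lt(max(abs(out$values - 2.5)), 1e-9)

  # 32 s window puts both probe tones exactly on FFT bins
  fs <- 20; tt <- seq(0, 32 - 1 / fs, by = 1 / fs)
  mixed <- sin(2 * pi * 0.25 * tt) + sin(2 * pi * 9 * tt)
  tr <- motion_trace(matrix(mixed, ncol = 1), fs)
  filt <- smooth_and_filter(tr, 1, 2)
  amp_at <- function(v, f) {
    sp <- abs(fft(v)) / length(v)
    k <- round(f * length(v) / fs) + 1
    2 * sp[k]
  }
  expect_lt(amp_at(drop(filt$values), 9), 0.05 * amp_at(mixed, 9))
  expect_gt(amp_at(drop(filt$values), 0.25), 0.9)

  # near-identity configuration passes a breathing-band signal unchanged
  breath <- motion_trace(matrix(sin(2 * pi * tt / 4), ncol = 1), fs)
  near <- smooth_and_filter(breath, 1, 9.9)
  rel_rms <- sqrt(mean((near$values - breath$values)^2)) /
    sqrt(mean(breath$values^2))
  expect_lt(rel_rms, 0.01)

  expect_error(smooth_and_filter(tr, 1, 10), "cutoff")
})

test_that("standardization is exact and invertible", {
  tr <- motion_trace(cbind(x = c(1, 2, 3), y = c(10, 20, 30),
                           z = c(-1, 0, 1)), 20)
  st <- standardize(tr)
  expect_lt(max(abs(colMeans(st$trace$values))), 1e-9)
  expect_lt(max(abs(apply(st$trace$values, 2, sd) - 1)), 1e-9)

  back <- destandardize(st$trace, st$stats)
  expect_lt(max(abs(back$values - tr$values)), 1e-9)

  # applying given statistics (train stats onto test data)
  stats <- standardization_stats(mean = c(10, 0, 0), sd = c(2, 1, 1))
  tr2 <- motion_trace(cbind(c(10, 12), c(0, 0), c(0, 0)), 20)
  z <- standardize(tr2, stats)$trace
  expect_equal(z$values[, 1], c(0, 1))

  ident <- standardization_stats(rep(0, 3), rep(1, 3))
  expect_equal(destandardize(tr, ident)$values, tr$values)

  const <- motion_trace(cbind(rep(1, 5), rep(2, 5), 1:5), 20)
  expect_error(standardize(const), "positive")
})

test_that("preprocessing preserves length and metadata", {
  sess <- short_session(seed = 2, duration_s = 30)
  out <- preprocess_session(sess)
  expect_equal(trace_length(out$external), trace_length(sess$external))
  expect_equal(out$external$sampling_rate_hz,
               sess$external$sampling_rate_hz)
  expect_true(all(is.finite(out$internal$values)))
})
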