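#' Parameters of the synthetic breathing-trace generator
#'
#' The generator emulates quiet free breathing recorded at a chest surface:
#' a cos^(2n)-shaped (Lujan-type) waveform with cycle-to-cycle jitter of
#' period and amplitude, a slow linear baseline drift, and additive sensor
#' noise. Axis amplitudes default to the ordering seen in liver motion
#' studies: superior-inferior (y) largest, anterior-posterior (z)
#' intermediate, left-right (x) smallest.
#'
#' @param duration_s session length (s); volunteer sessions are 5-6 min.
#' @param sampling_rate_hz sampling rate (Hz), 20 by default.
#' @param amplitude_mm length-3 numeric, peak amplitude per axis (x, y, z).
#' @param mean_period_s mean breathing period (s).
#' @param period_jitter_sd cycle period SD as a fraction of the mean (< 0.5).
#' @param amplitude_jitter_sd cycle amplitude SD as a fraction of the mean.
#' @param lujan_exponent exponent n of the cos^(2n) waveform; larger n gives
#'   longer end-exhale rest.
#' @param baseline_drift_mm_per_min linear baseline drift rate.
#' @param noise_sd_mm additive Gaussian noise SD (mm).
#' @return an object of class `breathing_params`.
#' @export
breathing_params <- function(duration_s = 300,
                             sampling_rate_hz = 20,
                             amplitude_mm = c(x = 1.5, y = 8, z = 4),
                             mean_period_s = 4,
                             period_jitter_sd = 0.08,
                             amplitude_jitter_sd = 0.1,
                             lujan_exponent = 2,
                             baseline_drift_mm_per_min = 0.5,
                             noise_sd_mm = 0.05) {
  p <- list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
            amplitude_mm = rep_len(as.numeric(amplitude_mm), 3L),
            mean_period_s = mean_period_s,
            period_jitter_sd = period_jitter_sd,
            amplitude_jitter_sd = amplitude_jitter_sd,
            lujan_exponent = lujan_exponent,
            baseline_drift_mm_per_min = baseline_drift_mm_per_min,
            noise_sd_mm = noise_sd_mm)
  names(p$amplitude_mm) <- c("x", "y", "z")
  with(p, {
    if (duration_s <= 0 || sampling_rate_hz <= 0 || mean_period_s <= 0 ||
        any(amplitude_mm < 0) || period_jitter_sd < 0 ||
        amplitude_jitter_sd < 0 || noise_sd_mm < 0 || lujan_exponent < 1) {
      stop_arg("breathing parameters must be positive")
    }
    if (period_jitter_sd >= 0.5) stop_arg("period_jitter_sd must be < 0.5")
    if (sampling_rate_hz < 2 / mean_period_s) {
      stop_arg("sampling rate below twice the breathing frequency")
    }
  })
  structure(p, class = "breathing_params")
}

#' Parameters of the external-to-internal coupling
#'
#' The internal liver trace is modelled as a lagged, slowly drifting affine
#' (optionally quadratic) transform of the external surface trace plus
#' noise; the gain drift makes the external/internal relationship
#' non-stationary, which is what the cumulative model-update protocol is
#' designed to expose.
#'
#' @param gain per-axis multiplicative coupling (recycled to 3).
#' @param gain_drift_per_min fractional gain change per minute.
#' @param lag_s internal lag behind the external signal (s); must be shorter
#'   than half a breathing period in magnitude.
#' @param offset_mm additive offset (mm).
#' @param internal_noise_sd_mm additive Gaussian noise on the internal
#'   trace (mm).
#' @param nonlinearity quadratic coefficient q of the coupling (per mm).
#' @return an object of class `correlation_params`.
#' @export
correlation_params <- function(gain = 0.8,
                               gain_drift_per_min = 0.05,
                               lag_s = 0.15,
                               offset_mm = 1.0,
                               internal_noise_sd_mm = 0.05,
                               nonlinearity = 0) {
  if (any(gain <= 0)) stop_arg("gain must be positive")
  if (internal_noise_sd_mm < 0) stop_arg("noise SD must be >= 0")
  structure(list(gain = rep_len(as.numeric(gain), 3L),
                 gain_drift_per_min = gain_drift_per_min,
                 lag_s = lag_s, offset_mm = offset_mm,
                 internal_noise_sd_mm = internal_noise_sd_mm,
                 nonlinearity = nonlinearity),
            class = "correlation_params")
}

#' Simulate an external chest-surface trace
#'
#' Each breathing cycle k draws a period and an amplitude from Gaussians
#' around the configured means, and contributes
#' `a_k * sin^(2n)(pi * t' / tau_k)` over its span (the sin form places the
#' cycle boundaries at end-exhale, so amplitude changes splice smoothly at
#' zero displacement). All three axes share the cycle timing and fractional
#' amplitude jitter - they are the same breath - and differ by their axis
#' amplitude; noise is drawn independently per axis.
#'
#' @param params a [breathing_params()].
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   output.
#' @return a [motion_trace()].
#' @export
simulate_external <- function(params, seed) {
  stopifnot(inherits(params, "breathing_params"))
  with_seed(seed, {
    fs <- params$sampling_rate_hz
    n <- round(params$duration_s * fs)
    tt <- (seq_len(n) - 1L) / fs

    # draw enough cycles to cover the session
    n_cyc <- ceiling(2 * params$duration_s / params$mean_period_s) + 4L
    tau <- rnorm(n_cyc, params$mean_period_s,
                 params$period_jitter_sd * params$mean_period_s)
    tau <- pmax(tau, 0.5 * params$mean_period_s)
    amp_frac <- pmax(rnorm(n_cyc, 1, params$amplitude_jitter_sd), 0.1)
    starts <- c(0, cumsum(tau))
    cyc <- findInterval(tt, starts)            # cycle index of each sample
    phase <- (tt - starts[cyc]) / tau[cyc]     # in [0, 1)
    shape <- sin(pi * phase)^(2 * params$lujan_exponent)
    drift <- params$baseline_drift_mm_per_min * tt / 60

    vals <- sapply(seq_len(3L), function(j) {
      params$amplitude_mm[j] * amp_frac[cyc] * shape + drift +
        rnorm(n, 0, params$noise_sd_mm)
    })
    colnames(vals) <- c("x", "y", "z")
    motion_trace(vals, fs)
  })
}

#' Derive an internal liver trace from an external trace
#'
#' Applies the coupling
#' `internal(t) = g(t) * e(t - lag) + offset + q * e(t - lag)^2 + noise`,
#' with `g(t) = gain * (1 + drift * t / 60)`. The lag is applied by linear
#' interpolation on the sample grid; samples whose lagged time falls before
#' the trace start are clamped to the first sample.
#'
#' @param external a [motion_trace()].
#' @param corr a [correlation_params()].
#' @param seed integer seed for the internal noise stream.
#' @return a [motion_trace()] aligned sample-by-sample with `external`.
#' @export
derive_internal <- function(external, corr, seed) {
  stopifnot(inherits(external, "motion_trace"),
            inherits(corr, "correlation_params"))
  n <- trace_length(external)
  tt <- trace_times(external)
  if (abs(corr$lag_s) >= tt[n] - tt[1]) {
    stop_arg("lag exceeds the trace duration")
  }
  with_seed(seed, {
    g_t <- corr$gain_drift_per_min # fraction per minute
    vals <- sapply(seq_len(ncol(external$values)), function(j) {
      e_lag <- approx(tt, external$values[, j], xout = tt - corr$lag_s,
                      rule = 2)$y
      gain_t <- corr$gain[j] * (1 + g_t * (tt - tt[1]) / 60)
      gain_t * e_lag + corr$offset_mm + corr$nonlinearity * e_lag^2 +
        rnorm(n, 0, corr$internal_noise_sd_mm)
    })
    colnames(vals) <- colnames(external$values)
    motion_trace(vals, external$sampling_rate_hz, external$start_time_s)
  })
}

#' Simulate a full paired session
#'
#' Composes [simulate_external()] (seeded with `seed`) and
#' [derive_internal()] (seeded with `seed + 1`, a fixed documented
#' derivation, so the two noise streams are independent but reproducible).
#'
#' @param params a [breathing_params()].
#' @param corr a [correlation_params()].
#' @param seed integer seed.
#' @return a [paired_traces()].
#' @examples
#' sess <- simulate_session(breathing_params(duration_s = 60),
#'                          correlation_params(), seed = 1)
#' sess
#' @export
simulate_session <- function(params = breathing_params(),
                             corr = correlation_params(),
                             seed = 1L) {
  ext <- simulate_external(params, seed)
  int <- derive_internal(ext, corr, seed + 1L)
  paired_traces(ext, int)
}

#' Write a simulated session to disk
#'
#' Writes `external.csv` and `internal.csv` in the package trace format plus
#' `truth.yaml` holding the generating parameters, which downstream recovery
#' tests treat as ground truth.
#'
#' @param params a [breathing_params()].
#' @param corr a [correlation_params()].
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_session <- function(params, corr, seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sess <- simulate_session(params, corr, seed)
  write_trace_csv(sess$external, file.path(dir, "external.csv"))
  write_trace_csv(sess$internal, file.path(dir, "internal.csv"))
  truth <- list(seed = as.integer(seed),
                breathing = unclass(params),
                coupling = unclass(corr))
  truth$breathing$amplitude_mm <- as.list(params$amplitude_mm)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
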