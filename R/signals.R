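#' Resample a trace to a target length
#'
#' Linear interpolation on a uniform grid spanning the original time range.
#' Used to bring an external surface trace to the exact length of the
#' simultaneously recorded internal trace before pairing.
#'
#' @param trace a [motion_trace()].
#' @param target_length desired sample count (>= 2).
#' @return a [motion_trace()] of `target_length` samples; the first and last
#'   samples equal the original endpoints exactly.
#' @export
resample_to_length <- function(trace, target_length) {
  stopifnot(inherits(trace, "motion_trace"))
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < 2L) {
    stop_arg("'target_length' must be an integer >= 2")
  }
  n <- trace_length(trace)
  if (target_length == n) return(trace)
  t_old <- trace_times(trace)
  t_new <- seq(t_old[1], t_old[n], length.out = target_length)
  vals <- apply(trace$values, 2, function(v) {
    approx(t_old, v, xout = t_new, method = "linear")$y
  })
  duration <- t_old[n] - t_old[1]
  motion_trace(vals, sampling_rate_hz = (target_length - 1L) / duration,
               start_time_s = trace$start_time_s)
}

#' Replace outlier samples by the rolling median (Hampel rule)
#'
#' Samples deviating from the centered rolling median by more than
#' `n_mad * 1.4826 * MAD` are replaced by that median. Replacement rather
#' than deletion keeps the sampling grid uniform, which the downstream
#' sliding-window datasets require. Near the trace edges the window is
#' truncated to the available samples.
#'
#' @param trace a [motion_trace()].
#' @param window odd window width in samples (>= 3).
#' @param n_mad rejection threshold in robust standard deviations.
#' @return a [motion_trace()] of unchanged length.
#' @note Once genuine spikes are replaced, a second pass is a no-op. When
#'   the threshold is pushed down to the noise scale, however, replacing a
#'   borderline sample shrinks the local MAD and can expose further
#'   borderline neighbours on a repeat pass; thresholds of 3 robust SDs or
#'   more on breathing-scale signals are comfortably clear of this regime.
#' @export
remove_outliers <- function(trace, window = 7L, n_mad = 3) {
  stopifnot(inherits(trace, "motion_trace"))
  window <- as.integer(window)
  n <- trace_length(trace)
  if (window < 3L || window %% 2L == 0L) {
    stop_arg("'window' must be an odd integer >= 3")
  }
  if (window >= n) stop_arg("'window' must be smaller than the trace length")
  half <- window %/% 2L
  vals <- trace$values
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    out <- v
    for (k in seq_len(n)) {
      lo <- max(1L, k - half); hi <- min(n, k + half)
      win <- v[lo:hi]
      med <- median(win)
      sigma <- 1.4826 * median(abs(win - med))
      if (abs(v[k] - med) > n_mad * sigma) out[k] <- med
    }
    vals[, j] <- out
  }
  motion_trace(vals, trace$sampling_rate_hz, trace$start_time_s)
}

#' Smooth and low-pass filter a trace
#'
#' A centered moving average of width `smooth_window` (edges padded by
#' replicating the end samples) followed by a zero-phase 4th-order
#' Butterworth low-pass applied forward and backward
#' ([signal::filtfilt()]). Zero-phase filtering matters here: a causal
#' filter would add group delay, i.e. exactly the kind of latency the
#' tracker is built to remove. Breathing energy sits below ~1 Hz, so the
#' default 2 Hz cutoff keeps the waveform and removes sensor noise.
#'
#' @param trace a [motion_trace()].
#' @param smooth_window odd moving-average width in samples (1 disables).
#' @param cutoff_hz low-pass cutoff; must be below the Nyquist frequency.
#' @param order Butterworth order.
#' @return a [motion_trace()] of unchanged length. Constant signals pass
#'   through unchanged (unit DC gain).
#' @export
smooth_and_filter <- function(trace, smooth_window = 5L, cutoff_hz = 2,
                              order = 4L) {
  stopifnot(inherits(trace, "motion_trace"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop_arg("'smooth_window' must be an odd integer >= 1")
  }
  nyq <- trace$sampling_rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop_arg("'cutoff_hz' must lie in (0, ", nyq, ")")
  }
  n <- trace_length(trace)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  vals <- apply(trace$values, 2, function(v) {
    if (smooth_window > 1L) {
      half <- smooth_window %/% 2L
      padded <- c(rep(v[1], half), v, rep(v[n], half))
      v <- as.numeric(stats::filter(padded, rep(1 / smooth_window,
                                                smooth_window),
                                    sides = 2))[(half + 1L):(half + n)]
    }
    # filtfilt handles its own edge extension; remove the mean first so the
    # transient correction acts on a zero-baseline signal
    mu <- mean(v)
    signal::filtfilt(bf, v - mu) + mu
  })
  motion_trace(vals, trace$sampling_rate_hz, trace$start_time_s)
}

#' Per-axis standardization statistics
#' @param mean,sd numeric vectors of per-axis mean and standard deviation
#'   (mm); `sd` must be strictly positive.
#' @return an object of class `standardization_stats`.
#' @export
standardization_stats <- function(mean, sd) {
  if (length(mean) != length(sd)) stop_arg("mean/sd length mismatch")
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop_arg("standard deviation must be positive on every axis ",
             "(degenerate constant axis?)")
  }
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "standardization_stats")
}

#' Z-score a trace
#'
#' When `stats` is `NULL` the per-axis mean and standard deviation are
#' computed from this trace; otherwise the supplied statistics are applied,
#' which is how training-set statistics are carried onto test data to avoid
#' leakage.
#'
#' @param trace a [motion_trace()].
#' @param stats optional [standardization_stats()].
#' @return list with elements `trace` (standardized) and `stats` (the
#'   statistics used).
#' @export
standardize <- function(trace, stats = NULL) {
  stopifnot(inherits(trace, "motion_trace"))
  if (is.null(stats)) {
    mu <- colMeans(trace$values)
    sigma <- apply(trace$values, 2, sd)
    stats <- standardization_stats(mu, sigma)
  } else {
    stopifnot(inherits(stats, "standardization_stats"))
    if (length(stats$mean) != ncol(trace$values)) {
      stop_arg("stats dimension does not match trace axes")
    }
  }
  vals <- sweep(sweep(trace$values, 2, stats$mean, "-"), 2, stats$sd, "/")
  list(trace = motion_trace(vals, trace$sampling_rate_hz,
                            trace$start_time_s),
       stats = stats)
}

#' Invert [standardize()]
#' @param trace a standardized [motion_trace()].
#' @param stats the [standardization_stats()] used to standardize it.
#' @return a [motion_trace()] back on the mm scale.
#' @export
destandardize <- function(trace, stats) {
  stopifnot(inherits(trace, "motion_trace"),
            inherits(stats, "standardization_stats"))
  vals <- sweep(sweep(trace$values, 2, stats$sd, "*"), 2, stats$mean, "+")
  motion_trace(vals, trace$sampling_rate_hz, trace$start_time_s)
}

# vector helpers used internally where a full trace object is overkill
std_apply <- function(x, mean, sd) (x - mean) / sd
std_invert <- function(z, mean, sd) z * sd + mean

#' Standard preprocessing pipeline
#'
#' Outlier replacement then smoothing/filtering, applied identically to the
#' external and internal traces of a session. Standardization is not done
#' here: it belongs to model training, where statistics must come from the
#' training portion only.
#'
#' @param paired a [paired_traces()].
#' @param window,n_mad Hampel parameters, see [remove_outliers()].
#' @param smooth_window,cutoff_hz see [smooth_and_filter()].
#' @return a preprocessed [paired_traces()].
#' @export
preprocess_session <- function(paired, window = 7L, n_mad = 3,
                               smooth_window = 5L, cutoff_hz = 2) {
  stopifnot(inherits(paired, "paired_traces"))
  fix <- function(tr) {
    smooth_and_filter(remove_outliers(tr, window, n_mad),
                      smooth_window, cutoff_hz)
  }
  paired_traces(fix(paired$external), fix(paired$internal))
}
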