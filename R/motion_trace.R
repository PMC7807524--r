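#' Uniformly sampled 3-axis motion trace
#'
#' A `motion_trace` holds displacement samples of one monitored point along
#' the three patient axes used in motion management: x = left-right,
#' y = superior-inferior, z = anterior-posterior. Samples are in millimetres
#' on a uniform time grid.
#'
#' @param values numeric matrix with one row per sample and columns
#'   `x`, `y`, `z` (mm). A vector is accepted for a single-axis trace and is
#'   recycled into a one-column matrix.
#' @param sampling_rate_hz samples per second (> 0).
#' @param start_time_s wall-clock offset of the first sample (s).
#' @return An object of class `motion_trace`: a list with elements `values`
#'   (matrix), `sampling_rate_hz`, `start_time_s`.
#' @examples
#' tr <- motion_trace(cbind(x = sin(1:100 / 10), y = 0, z = 0), 20)
#' trace_length(tr)
#' @export
motion_trace <- function(values, sampling_rate_hz, start_time_s = 0) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- c("x", "y", "z")[seq_len(ncol(values))]
  }
  if (nrow(values) < 2L) {
    stop_arg("a motion trace needs at least 2 samples per axis")
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop_arg("'sampling_rate_hz' must be a single positive number")
  }
  structure(
    list(values = values,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         start_time_s = as.numeric(start_time_s)),
    class = "motion_trace"
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d samples x %d axes @ %.6g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate_hz,
              nrow(x$values) / x$sampling_rate_hz))
  invisible(x)
}

#' Number of samples per axis in a trace
#' @param trace a [motion_trace()].
#' @return integer sample count.
#' @export
trace_length <- function(trace) nrow(trace$values)

#' Sample times of a trace
#' @param trace a [motion_trace()].
#' @return numeric vector of times (s), `start_time_s + k / rate`.
#' @export
trace_times <- function(trace) {
  trace$start_time_s +
    (seq_len(trace_length(trace)) - 1L) / trace$sampling_rate_hz
}

#' Extract a contiguous slice of a trace
#' @param trace a [motion_trace()].
#' @param from,to first and last sample index (1-based, inclusive).
#' @return a [motion_trace()] covering the selected samples; `start_time_s`
#'   is advanced so sample times are preserved.
#' @export
trace_slice <- function(trace, from, to) {
  n <- trace_length(trace)
  if (from < 1L || to > n || from >= to) {
    stop_arg("invalid slice [", from, ", ", to, "] for trace of length ", n)
  }
  motion_trace(trace$values[from:to, , drop = FALSE],
               trace$sampling_rate_hz,
               trace$start_time_s + (from - 1L) / trace$sampling_rate_hz)
}

#' Paired external/internal session
#'
#' Couples one chest-surface (external) trace with the simultaneously
#' recorded liver (internal) trace. Sample k of both traces refers to the
#' same instant; the pair must be length-aligned (use [resample_to_length()]
#' on the external trace first when the acquisition lengths differ).
#'
#' @param external,internal [motion_trace()] objects of identical length and
#'   sampling rate.
#' @return An object of class `paired_traces`.
#' @export
paired_traces <- function(external, internal) {
  stopifnot(inherits(external, "motion_trace"),
            inherits(internal, "motion_trace"))
  if (trace_length(external) != trace_length(internal)) {
    stop_arg("external and internal traces must have equal length; got ",
             trace_length(external), " and ", trace_length(internal))
  }
  if (abs(external$sampling_rate_hz - internal$sampling_rate_hz) > 1e-9) {
    stop_arg("external and internal sampling rates differ")
  }
  structure(list(external = external, internal = internal),
            class = "paired_traces")
}

#' @export
print.paired_traces <- function(x, ...) {
  cat("<paired_traces>\n  external: ")
  print(x$external)
  cat("  internal: ")
  print(x$internal)
  invisible(x)
}

#' Slice a paired session
#' @param paired a [paired_traces()].
#' @param from,to sample index range (1-based, inclusive).
#' @return a [paired_traces()] restricted to the range.
#' @export
paired_slice <- function(paired, from, to) {
  paired_traces(trace_slice(paired$external, from, to),
                trace_slice(paired$internal, from, to))
}

#' Read a motion trace from CSV
#'
#' Expects the plain-text trace format used throughout the package: header
#' `time_s,x_mm,y_mm,z_mm`, one row per sample, '.' decimal separator. The
#' sampling rate is inferred as the reciprocal of the median time step.
#'
#' @param path CSV file path.
#' @return a [motion_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  df <- read.csv(path)
  need <- c("time_s", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop_arg("trace CSV must have columns ", paste(need, collapse = ", "))
  }
  tt <- df$time_s
  if (length(tt) < 2L) stop_arg("trace CSV needs at least 2 rows")
  dt <- diff(tt)
  if (any(dt <= 0)) stop_arg("time column must be strictly increasing")
  vals <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  colnames(vals) <- c("x", "y", "z")
  if (!all(is.finite(vals))) stop_arg("trace contains non-finite values")
  motion_trace(vals, sampling_rate_hz = 1 / median(dt), start_time_s = tt[1])
}

#' Write a motion trace to CSV
#'
#' Inverse of [read_trace_csv()]; values are written at full double
#' precision so a round trip reproduces the trace exactly.
#'
#' @param trace a [motion_trace()] with three axes.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  if (ncol(trace$values) != 3L) {
    stop_arg("write_trace_csv expects a 3-axis trace")
  }
  df <- data.frame(time_s = trace_times(trace),
                   x_mm = trace$values[, 1],
                   y_mm = trace$values[, 2],
                   z_mm = trace$values[, 3])
  # format() at 17 significant digits keeps the round trip exact
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
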