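#' Root-mean-square error
#' @param y,y_hat true and predicted sequences of equal nonzero length.
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  check_pair(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return `mean(abs(y - y_hat))`.
#' @export
mae <- function(y, y_hat) {
  check_pair(y, y_hat)
  mean(abs(y - y_hat))
}

#' Maximum absolute error
#' @inheritParams rmse
#' @return `max(abs(y - y_hat))`.
#' @export
max_ae <- function(y, y_hat) {
  check_pair(y, y_hat)
  max(abs(y - y_hat))
}

check_pair <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat)) {
    stop_arg("sequences must have equal nonzero length")
  }
  invisible(NULL)
}

#' Per-axis error report
#'
#' Computes RMSE, MAE and maximum absolute error per axis, in the units of
#' the supplied matrices (mm when called, as everywhere in this package, on
#' destandardized values). For any data the three metrics satisfy
#' `MAE <= RMSE <= MAX_AE`.
#'
#' @param y,y_hat numeric matrices (rows = samples, columns = axes) of true
#'   and predicted positions.
#' @param context optional named list of labels (model kind, latency, ...)
#'   stored alongside the numbers.
#' @return an object of class `metrics_report`: data frame with columns
#'   `axis`, `rmse`, `mae`, `max_ae`, `n`, with `context` as attribute.
#' @export
metrics_report <- function(y, y_hat, context = list()) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!identical(dim(y), dim(y_hat))) stop_arg("dimension mismatch")
  axes <- colnames(y) %||% paste0("axis", seq_len(ncol(y)))
  out <- data.frame(
    axis = axes,
    rmse = vapply(seq_len(ncol(y)), function(j) rmse(y[, j], y_hat[, j]), 0),
    mae = vapply(seq_len(ncol(y)), function(j) mae(y[, j], y_hat[, j]), 0),
    max_ae = vapply(seq_len(ncol(y)), function(j) max_ae(y[, j], y_hat[, j]),
                    0),
    n = nrow(y),
    row.names = NULL)
  attr(out, "context") <- context
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  ctx <- attr(x, "context")
  if (length(ctx)) {
    cat("context:", paste(names(ctx), unlist(ctx), sep = "=",
                          collapse = ", "), "\n")
  }
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report a [metrics_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  payload <- list(context = attr(report, "context"),
                  metrics = as.data.frame(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
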