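#' Split a paired session into six chronological parts
#'
#' Contiguous, non-overlapping segments C1..C6 with lengths proportional to
#' `proportions` (default 1:2:2:2:2:1). Lengths are rounded by the
#' largest-remainder rule so they sum exactly to the session length;
#' remainder ties go to the earlier segment. Concatenating the segments
#' reproduces the session exactly.
#'
#' @param paired a [paired_traces()].
#' @param proportions six positive weights.
#' @return list of six [paired_traces()] segments, named `C1`..`C6`.
#' @export
split_six_parts <- function(paired, proportions = c(1, 2, 2, 2, 2, 1)) {
  stopifnot(inherits(paired, "paired_traces"))
  if (length(proportions) != 6L || any(proportions <= 0)) {
    stop_arg("'proportions' must be six positive numbers")
  }
  n <- trace_length(paired$external)
  if (n < 60L) stop_arg("session too short to split (need >= 60 samples)")
  exact <- n * proportions / sum(proportions)
  len <- floor(exact)
  rem <- n - sum(len)
  if (rem > 0) {
    frac <- exact - len
    # largest remainder first; ties resolved toward earlier segments
    give <- order(-frac, seq_along(frac))[seq_len(rem)]
    len[give] <- len[give] + 1L
  }
  if (any(len < 2L)) stop_arg("session too short for these proportions")
  ends <- cumsum(len)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- lapply(seq_len(6L), function(k) {
    paired_slice(paired, starts[k], ends[k])
  })
  names(out) <- paste0("C", 1:6)
  out
}

#' Configuration of the cumulative model-update study
#'
#' @param proportions six split weights (see [split_six_parts()]).
#' @param repeats trainings per update group (each with its own seed).
#' @param model_kind correlator kind, `"lstm"` (default) or `"svr"`.
#' @param W correlator window length.
#' @param lstm_cfg,lstm_train,svr_cfg optional model overrides forwarded to
#'   [train_correlator()].
#' @param seed_base first seed; repeat r of any group uses
#'   `seed_base + r - 1`.
#' @return an object of class `update_study_config`.
#' @export
update_study_config <- function(proportions = c(1, 2, 2, 2, 2, 1),
                                repeats = 5L,
                                model_kind = c("lstm", "svr"),
                                W = 20L,
                                lstm_cfg = NULL, lstm_train = NULL,
                                svr_cfg = NULL,
                                seed_base = 0L) {
  model_kind <- match.arg(model_kind)
  if (repeats < 1L) stop_arg("repeats must be >= 1")
  structure(list(proportions = proportions, repeats = as.integer(repeats),
                 model_kind = model_kind, W = as.integer(W),
                 lstm_cfg = lstm_cfg, lstm_train = lstm_train,
                 svr_cfg = svr_cfg, seed_base = as.integer(seed_base)),
            class = "update_study_config")
}

#' Run the cumulative correlation-model update study
#'
#' Splits the session into C1..C6, then performs five groups of
#' assessments: update k trains the external/internal correlator from
#' scratch on the cumulative segment C1+...+Ck and evaluates it on the
#' fixed final segment C6. Each group is repeated `repeats` times with
#' consecutive seeds; the per-group mean RMSE and MAE over repeats are
#' reported per axis, pooled across axes (root mean square over axes for
#' RMSE, mean for MAE), and normalized to the fifth update.
#'
#' @param paired a preprocessed [paired_traces()] session.
#' @param config an [update_study_config()].
#' @return an object of class `update_study_result`: list with `raw`
#'   (per repeat x update x axis data frame), `summary` (per update x axis
#'   means and normalized values), and `pooled` (per update, across axes).
#' @export
run_update_study <- function(paired, config = update_study_config()) {
  stopifnot(inherits(paired, "paired_traces"),
            inherits(config, "update_study_config"))
  parts <- split_six_parts(paired, config$proportions)
  lens <- vapply(parts, function(p) trace_length(p$external), 0L)
  test_seg <- parts$C6

  rows <- list()
  for (k in 1:5) {
    train_end <- sum(lens[1:k])
    train_seg <- paired_slice(paired, 1L, train_end)
    for (r in seq_len(config$repeats)) {
      corr <- train_correlator(train_seg, config$model_kind,
                               W = config$W, train_fraction = 1,
                               lstm_cfg = config$lstm_cfg,
                               lstm_train = config$lstm_train,
                               svr_cfg = config$svr_cfg,
                               seed = config$seed_base + r - 1L)
      m <- evaluate_correlator(corr, test_seg)
      rows[[length(rows) + 1L]] <-
        data.frame(update = k, repeat_id = r, axis = m$axis,
                   rmse = m$rmse, mae = m$mae)
    }
  }
  raw <- do.call(rbind, rows)

  agg <- stats::aggregate(cbind(rmse, mae) ~ update + axis, data = raw,
                          FUN = mean)
  names(agg)[names(agg) == "rmse"] <- "mean_rmse"
  names(agg)[names(agg) == "mae"] <- "mean_mae"
  ref <- agg[agg$update == 5L, c("axis", "mean_rmse", "mean_mae")]
  agg$norm_rmse <- agg$mean_rmse /
    ref$mean_rmse[match(agg$axis, ref$axis)]
  agg$norm_mae <- agg$mean_mae / ref$mean_mae[match(agg$axis, ref$axis)]
  agg <- agg[order(agg$update, agg$axis), ]
  rownames(agg) <- NULL

  pooled <- do.call(rbind, lapply(1:5, function(k) {
    a <- agg[agg$update == k, ]
    data.frame(update = k,
               mean_rmse = sqrt(mean(a$mean_rmse^2)),
               mean_mae = mean(a$mean_mae))
  }))
  pooled$norm_rmse <- pooled$mean_rmse / pooled$mean_rmse[5]
  pooled$norm_mae <- pooled$mean_mae / pooled$mean_mae[5]

  structure(list(raw = raw, summary = agg, pooled = pooled,
                 segment_lengths = lens, config = config),
            class = "update_study_result")
}

#' @export
print.update_study_result <- function(x, ...) {
  cat("Cumulative correlation-model update study (",
      x$config$model_kind, " correlator, ", x$config$repeats,
      " repeats)\n", sep = "")
  cat("segment lengths:", paste(x$segment_lengths, collapse = " "), "\n")
  print(x$pooled, digits = 4)
  invisible(x)
}

#' Write update-study results to disk
#' @param result an `update_study_result`.
#' @param json_path,csv_path output files (either may be NULL to skip).
#' @return invisibly, the result.
#' @export
write_update_study <- function(result, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(summary = result$summary,
                              pooled = result$pooled,
                              raw = result$raw,
                              segment_lengths = result$segment_lengths),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) write.csv(result$summary, csv_path,
                                    row.names = FALSE)
  invisible(result)
}
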