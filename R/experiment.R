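#' Configuration of a full tracking experiment
#'
#' Either point `external_csv`/`internal_csv` at a recorded session in the
#' package trace format, or leave them NULL to simulate a session with the
#' given generator parameters. One root `seed` fans out deterministically to
#' the stages (simulation uses `seed`, predictor training `seed + 100`,
#' correlator training `seed + 200`, the update study `seed + 300`), so any
#' stage can be re-run in isolation and reproduce its artifacts.
#'
#' @param out_dir output directory.
#' @param external_csv,internal_csv optional input CSV paths.
#' @param breathing,coupling generator parameters for the synthetic session
#'   (used when no CSVs are given).
#' @param latency_ms latencies to assess (ms).
#' @param kinds model kinds to train.
#' @param W window length (samples).
#' @param preprocess apply [preprocess_session()] first.
#' @param lstm_cfg,lstm_train,svr_cfg optional model overrides.
#' @param update_study run the cumulative update study as well.
#' @param seed root seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(out_dir,
                              external_csv = NULL, internal_csv = NULL,
                              breathing = breathing_params(),
                              coupling = correlation_params(),
                              latency_ms = c(50, 150, 200, 450),
                              kinds = c("lstm", "svr"),
                              W = 20L,
                              preprocess = TRUE,
                              lstm_cfg = NULL, lstm_train = NULL,
                              svr_cfg = NULL,
                              update_study = TRUE,
                              seed = 0L) {
  if (any(latency_ms < 0)) stop_arg("latencies must be >= 0")
  structure(list(out_dir = out_dir, external_csv = external_csv,
                 internal_csv = internal_csv, breathing = breathing,
                 coupling = coupling, latency_ms = latency_ms,
                 kinds = kinds, W = as.integer(W),
                 preprocess = isTRUE(preprocess),
                 lstm_cfg = lstm_cfg, lstm_train = lstm_train,
                 svr_cfg = svr_cfg,
                 update_study = isTRUE(update_study),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

exp_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full experiment pipeline
#'
#' simulate/load -> preprocess -> train predictors at every latency ->
#' train correlators -> integrated tracking -> update study, writing
#' per-stage JSON metric reports, model checkpoints, and a manifest to the
#' output directory. Deterministic given the config.
#'
#' @param config an [experiment_config()].
#' @return the manifest (named list of written artifact paths), invisibly.
#' @export
run_full_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  keep <- function(name, path) manifest[[name]] <<- path

  if (!is.null(config$external_csv)) {
    exp_log("load", "reading session from CSV")
    if (!file.exists(config$external_csv) ||
        !file.exists(config$internal_csv %||% "")) {
      stop_arg("input trace files not found")
    }
    ext <- read_trace_csv(config$external_csv)
    int <- read_trace_csv(config$internal_csv)
    ext <- resample_to_length(ext, trace_length(int))
    sess <- paired_traces(ext, int)
  } else {
    exp_log("simulate", "generating synthetic session (seed ",
            config$seed, ")")
    sess <- simulate_session(config$breathing, config$coupling,
                             config$seed)
  }

  if (config$preprocess) {
    exp_log("preprocess", "outlier replacement + smoothing + filtering")
    sess <- preprocess_session(sess)
  }

  reports <- list()
  correlators <- list()
  for (kind in config$kinds) {
    exp_log("train-corr", kind, "corr")
    corr <- train_correlator(sess, kind, W = config$W,
                             lstm_cfg = config$lstm_cfg,
                             lstm_train = config$lstm_train,
                             svr_cfg = config$svr_cfg,
                             seed = config$seed + 200L)
    correlators[[kind]] <- corr
    p <- file.path(config$out_dir, sprintf("corr_%s.json", kind))
    write_metrics_json(corr$metrics, p)
    keep(sprintf("corr_%s", kind), p)
    ck <- file.path(config$out_dir, sprintf("corr_%s.ckpt.json", kind))
    save_checkpoint(corr, ck)
    keep(sprintf("corr_%s_ckpt", kind), ck)
    reports[[length(reports) + 1L]] <- corr$metrics
  }

  for (kind in config$kinds) {
    for (L in config$latency_ms) {
      exp_log("train-pred", kind, "pred @ ", L, " ms")
      pred <- train_external_predictor(sess$external, kind,
                                       latency_ms = L, W = config$W,
                                       lstm_cfg = config$lstm_cfg,
                                       lstm_train = config$lstm_train,
                                       svr_cfg = config$svr_cfg,
                                       seed = config$seed + 100L)
      p <- file.path(config$out_dir,
                     sprintf("pred_%s_%dms.json", kind, as.integer(L)))
      write_metrics_json(pred$metrics, p)
      keep(sprintf("pred_%s_%dms", kind, as.integer(L)), p)
      reports[[length(reports) + 1L]] <- pred$metrics

      exp_log("track", "integrated ", kind, " @ ", L, " ms")
      trk <- integrated_tracker(pred, correlators[[kind]])
      res <- track_session(trk, sess)
      p2 <- file.path(config$out_dir,
                      sprintf("integrated_%s_%dms.json", kind,
                              as.integer(L)))
      write_metrics_json(res$metrics, p2)
      keep(sprintf("integrated_%s_%dms", kind, as.integer(L)), p2)
    }
  }

  if (config$update_study) {
    exp_log("update-study", "cumulative retraining protocol")
    us <- run_update_study(sess, update_study_config(
      model_kind = config$kinds[1], W = config$W,
      lstm_cfg = config$lstm_cfg, lstm_train = config$lstm_train,
      svr_cfg = config$svr_cfg,
      seed_base = config$seed + 300L))
    pj <- file.path(config$out_dir, "update_study.json")
    pc <- file.path(config$out_dir, "update_study.csv")
    write_update_study(us, pj, pc)
    keep("update_study_json", pj)
    keep("update_study_csv", pc)
  }

  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  keep("manifest", mp)
  exp_log("done", "artifacts in ", config$out_dir)
  invisible(manifest)
}
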