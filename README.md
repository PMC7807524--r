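# livertrack

Indirect real-time tracking of internal liver motion from external
chest-surface breathing signals, for use in surface-guided radiation
therapy (SGRT) motion management.

Optical surface monitoring is non-invasive and dose-free, but it measures a
*surrogate*: the chest surface, not the liver. And every tracking chain has
a system latency — a target moving at 20 mm/s drifts 2 mm during a 100 ms
latency and 8 mm during 400 ms. `livertrack` implements the two models that
make surrogate-based tracking work, and their composition:

- **External predictor** (`train_external_predictor()`): forecasts the
  surface signal S at time *t + i* from a 20-sample window ending at *t*,
  cancelling a latency of *i* sampling steps (50/150/200/450 ms at 20 Hz
  map to i = 1/3/4/9).
- **External/internal correlator** (`train_correlator()`): maps a surface
  window ending at *t* to the internal liver position I at the same
  instant.
- **Integrated tracker** (`integrated_tracker()`, `track_session()`,
  `predict_internal()`): predicts I at *t + i* from surface history up to
  *t* by filling the last *i* window entries with predicted surface values.

Each stage comes in two variants, trained per axis (x = left-right,
y = superior-inferior, z = anterior-posterior) on standardized sliding
windows with a chronological 9:1 train/test split:

- a **peephole LSTM** — the memory-block forward pass (input/forget/output
  gates with diagonal peephole connections, output gate reading the
  *current* cell value) is implemented from scratch, with a pure-R
  reference cell (`lstm_cell_step()`), a compiled training backend with
  hand-derived backpropagation through time, and minibatch Adam on MSE
  (learning rate 0.001, batch 64, 60/40 epochs);
- an **epsilon-insensitive SVR** with RBF kernel (gamma 0.1, C = 1000),
  fitted by SMO behind the package's model surface, with an exact dense
  dual-QP oracle (`fit_svr_qp()`) for verification.

The package also provides signal preprocessing (Hampel outlier
replacement, smoothing, zero-phase low-pass filtering, leak-free
standardization), RMSE/MAE/MAX\_AE reporting (`metrics_report()`), a seeded
generator of paired surface/liver sessions (`simulate_session()`) with
Lujan-type cos^(2n) breathing, cycle jitter, baseline drift and a drifting
affine external/internal coupling, and the cumulative model-update
protocol (`run_update_study()`): six chronological parts in proportion
1:2:2:2:2:1, five nested training sets, five repeats each, all evaluated
on the fixed final part and normalized to the fifth update.

## Worked example

```r
library(livertrack)

# a 5-minute paired session at 20 Hz, then the standard preprocessing
sess <- preprocess_session(simulate_session(breathing_params(),
                                            correlation_params(), seed = 0))

lc <- lstm_config(layers = 1, hidden = 16, dropout = 0)

pred <- train_external_predictor(sess$external, "lstm", latency_ms = 450,
                                 lstm_cfg = lc, seed = 0)
pred$metrics
#> context: model=lstmpred, latency_ms=450, steps=9
#>   axis   rmse    mae max_ae   n
#> 1    x 0.1786 0.1449 0.4662 598
#> 2    y 0.2338 0.1916 0.6477 598
#> 3    z 0.1422 0.1166 0.3811 598

persistence_report(sess$external, 450)$rmse   # the no-model baseline
#> [1] 0.395 2.093 1.047

corr <- train_correlator(sess, "lstm", lstm_cfg = lc, seed = 0)
corr$metrics$rmse
#> [1] 0.0653 0.2971 0.1250

trk <- integrated_tracker(pred, corr)
res <- track_session(trk, sess, eval_range = c(5401, 6000))
res$metrics
#> context: model=integrated, kind=lstm, latency_ms=450, steps=9, ...
#>   axis   rmse    mae max_ae   n
#> 1    x 0.2186 0.1825 0.5830 600
#> 2    y 0.3195 0.2601 0.8321 600
#> 3    z 0.1998 0.1682 0.4871 600
```

Read: with a 450 ms latency the trained LSTM predictor tracks the surface
to ~0.14-0.23 mm RMSE per axis where simply reporting the current position
would err by up to 2.1 mm; the correlator recovers the liver position to
~0.07-0.30 mm; and the integrated tracker — which has to do both jobs at
once — stays below the sum of the two stage errors on every axis.

The update study on the same session (its coupling gain drifts 5%/min):

```r
us <- run_update_study(sess, update_study_config(
  model_kind = "lstm", lstm_cfg = lc,
  lstm_train = lstm_train_config(epochs = 10), seed_base = 0))
us$pooled[, c("update", "mean_rmse", "norm_rmse")]
#>   update mean_rmse norm_rmse
#> 1      1    1.8468     6.330
#> 2      2    1.1389     3.904
#> 3      3    0.8159     2.797
#> 4      4    0.4780     1.638
#> 5      5    0.2917     1.000
```

Error falls monotonically as the training set grows toward the test
period — refreshing the correlator matters whenever the external/internal
relationship drifts.

A thin command-line front end over the same functions ships in
`inst/cli/livertrack.R` (subcommands `simulate`, `train-pred`,
`train-corr`, `track`, `update-study`, `run-all`).

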