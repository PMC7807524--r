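---
title: "Latency-compensated liver motion tracking from surface surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency-compensated liver motion tracking from surface surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface-guided radiation therapy (SGRT) monitors a patient's chest surface
optically during irradiation. For liver targets the surface is only a
surrogate: the quantity of clinical interest is the displacement of the
internal target (here, a liver landmark such as a vessel bifurcation), and
every real-time tracking chain has a system latency — typically tens to
hundreds of milliseconds between acquiring a surface frame and acting on
it. A point moving at 20 mm/s covers 2 mm during a 100 ms latency
(`latency_displacement_mm(100)`), and 8 mm during 400 ms, which is why
indirect tracking needs two models working together:

1. an **external predictor** that forecasts the surface signal `i` sampling
   steps ahead, cancelling the latency (at 20 Hz, latencies of 50/150/200/
   450 ms correspond to `i` = 1/3/4/9), and
2. an **external/internal correlator** that maps a window of surface motion
   ending at time *t* to the internal position at the same instant.

Their composition — predict the surface forward, then map the completed
window to the internal target — is the **integrated tracker**
(`integrated_tracker()`, `predict_internal()`, `track_session()`), which
outputs the internal position at *t + i* from surface history up to *t*.

Both stages are provided in two variants: a peephole LSTM network and an
epsilon-insensitive support vector regressor (SVR), trained per axis
(left-right x, superior-inferior y, anterior-posterior z) on sliding
windows of the standardized signal.

## Models

### Peephole LSTM

The recurrent unit is a classic memory block with input, forget and output
gates and diagonal *peephole* connections from the cell value to the gates.
Per cell and time step, with logistic-sigmoid gate activation and tanh cell
input/output:

* input gate and forget gate read the **previous** cell value through
  their peepholes,
* the cell updates as `s_t = f_t * s_{t-1} + i_t * tanh(a_c)`,
* the output gate reads the **current** cell value `s_t`,
* the block output is `h_t = o_t * tanh(s_t)`.

`lstm_cell_step()` is a plain-R reference implementation of exactly this
arithmetic (biases default to zero so the bias-free printed form of the
equations is reproduced verbatim); the training backend in `src/lstm.cpp`
is a vectorized re-implementation of the same equations with hand-derived
backpropagation through time, verified in the test suite against an
independent scalar-loop oracle (to 1e-10) and against central finite
differences of the loss (to 1e-5 relative).

Training (`train_lstm()`) is minibatch Adam on mean-squared error:
learning rate 0.001, batch 64, 60 epochs for the predictor and 40 for the
correlator, window length `W = 20` time steps, dropout (20% by default)
between stacked layers during training only. One integer seed fixes
initialization, shuffling and dropout masks, so runs are bit-reproducible.

### Epsilon-insensitive SVR

`fit_svr()` solves the standard eps-SVR problem — squared-norm
regularization plus C-weighted epsilon-insensitive loss — with an RBF
kernel (`gamma = 0.1`, `C = 1000`). Production fitting uses the libsvm SMO
solver behind the package's own model surface; `predict_svr()` evaluates
the support-vector expansion `f(x) = sum_i beta_i k(x_i, x) + b`
explicitly. `fit_svr_qp()` is an independent dense interior-point solution
of the same dual (box constraints `[0, C]`, balance constraint
`sum(beta) = 0`) used as ground truth in tests; the two solvers agree to
1e-4 at the training points and to 1e-6 in relative dual objective on
random 20-30-point instances.

The tube half-width epsilon deserves care. Any residual smaller than
epsilon is ignored by the loss, so epsilon mathematically caps the
attainable accuracy at roughly `epsilon * SD` of the target (the model is
fitted on standardized data). The package default (`epsilon = 0.1`) is a
conventional choice for noisy data, but on the synthetic sessions used in
the tests — where post-filtering noise is about 0.01-0.03 SD units — it
would bury both the affine-recovery accuracy and the latency dependence of
the predictor under a ~0.2 mm tube floor on the SI axis. All study runs
therefore set `epsilon = 0.01`, i.e. at the noise floor, and thin the SVR
training windows to every third window (`svr_stride = 3`): adjacent 20 Hz
windows overlap in 19 of 20 samples, and the thinning changes held-out
RMSE by under 2% while cutting the SMO cost several-fold.

## Data handling

Traces are uniformly sampled 3-axis displacement series in mm
(`motion_trace()`, CSV format `time_s,x_mm,y_mm,z_mm`). Preprocessing
(`preprocess_session()`) follows the usual surrogate-signal chain:

* **Hampel outlier replacement** (window 7, 3 robust SDs): samples far
  from the rolling median are replaced by it — replacement rather than
  deletion keeps the grid uniform for windowing;
* **smoothing** (5-sample centered moving average) and a **zero-phase
  4th-order Butterworth low-pass at 2 Hz**: breathing energy lies below
  1 Hz; zero-phase filtering is essential because a causal filter would
  add group delay, the very latency the tracker exists to remove;
* **standardization** per axis, with statistics computed on the training
  portion only and applied unchanged to test data; all reported metrics
  are in mm after destandardization.

Supervised sets are stride-1 sliding windows (`make_prediction_dataset()`,
`make_correlation_dataset()`), split 9:1 chronologically
(`chronological_split()`) — no shuffling across the boundary, so no
test-set leakage. The "1:1 length ratio" between inputs and targets is
realized as one scalar target per input window, which lets the LSTM and
the SVR consume identical supervised pairs; the alternative
sequence-to-sequence reading would preclude the shared-dataset design.

In the integrated tracker the correlator window at target time *t + i*
mixes observed samples (up to *t*) with predicted ones (the final *i*
entries), each predicted by the single i-step-ahead model applied to an
observed window — no recursive feedback of predictions into predictor
inputs. At `i = 0` the tracker collapses to the correlator exactly, which
the tests assert to machine precision.

## The synthetic session generator

Real paired surface/liver recordings — multi-minute free-breathing
sessions sampled at 20 Hz — are not bundled with the package, so the
generator produces sessions with the same structure:

* a Lujan-type `cos^(2n)` breathing waveform (implemented as
  `a_k sin^(2n)(pi t'/tau_k)` so cycle boundaries sit at end-exhale and
  amplitude changes splice continuously), `n = 2`, mean period 4 s;
* cycle-to-cycle jitter: period SD 8%, amplitude SD 10% — the cycles share
  timing across axes (they are the same breath) and differ by axis
  amplitude (x 1.5 mm, y 8 mm, z 4 mm, the usual LR < AP < SI ordering);
* linear baseline drift 0.5 mm/min and white sensor noise SD 0.05 mm;
* an internal trace that is a lagged (0.15 s), slowly drifting affine
  transform of the external trace: gain 0.8 growing 5%/min, offset 1 mm,
  optional quadratic term, internal noise SD 0.05 mm. The gain drift is
  deliberately linear — the simplest non-stationarity that makes model
  updating matter.

Defaults produce 300 s sessions (6000 samples/axis). Seeds fully determine
the output (`simulate_session()` uses `seed` for the external trace and
`seed + 1` for the internal noise stream).

What the generator does **not** emulate: hysteresis between inhale and
exhale paths, cough/talking events, cardiac contamination, phase-dependent
(rather than gain-drifting) external/internal decoupling, and measurement
dropouts. Passing tests on synthetic data therefore demonstrate that the
machinery is correct and that the qualitative phenomena (latency degrades
prediction; updating helps under drift) are reproduced — not that the
millimetre error levels transfer to any particular patient population.

## The cumulative update study

`run_update_study()` implements the verification protocol for refreshing
the correlator: the session is split chronologically into six parts
C1..C6 in proportion 1:2:2:2:2:1 (largest-remainder rounding), five
training sets C1, C1+C2, ..., C1+...+C5 are each used to retrain the
correlator from scratch five times (consecutive seeds), and every model is
evaluated on the fixed final part C6. Mean RMSE/MAE per update are
reported per axis and pooled (root-mean-square over axes for RMSE, mean
for MAE), and normalized to the fifth update, whose normalized value is 1
by construction. Under the default gain drift the error falls
monotonically from update 1 to 5; with no drift and no noise the
normalized curve is flat — both behaviours are asserted in the tests.

## Problem sizes and numerical choices

The shipped experiments (test suite and `scripts/acceptance.R`) run on
300 s default sessions with single-layer 8-cell LSTMs, the standard
optimizer settings (Adam 0.001, batch 64, 60/40 epochs), SVR
`epsilon = 0.01` with stride-3 training windows, and 10 epochs per repeat
inside the update study (25 retrainings). These sizes were chosen once as
the smallest configuration on which every qualitative property is stable
across seeds; the default `lstm_config()` (2 x 64 cells with 20% dropout)
remains the recommended starting point for real multi-session data.

Other numerical decisions:

* `latency_to_steps()` rounds to the nearest sample with half-sample ties
  rounded up.
* Six-part split rounding is largest-remainder, ties to the earlier
  segment, so segment lengths always sum to the session length.
* The lag in `derive_internal()` is applied by linear interpolation with
  clamping at the trace start.
* The QP oracle recovers the SVR offset as the midpoint of the interval of
  offsets minimizing the epsilon-insensitive loss (a point whenever a free
  support vector exists).
* Degenerate inputs fail fast: constant axes cannot be standardized,
  windows longer than the trace raise argument errors, non-monotone time
  columns are rejected at CSV load.

## Known limitations

* **RBF-SVR extrapolation under baseline drift.** The default session
  drifts by ~2.5 mm over 5 min, so late-session windows lie at the edge of
  the training distribution. The RBF expansion saturates there and
  acquires a small (~0.05 mm) axis-dependent bias that dominates the
  held-out error of `SVRpred` at short latencies and masks the latency
  dependence of its test RMSE on some axes; the same models' error on
  held-in data grows strictly with latency (0.005/0.007/0.010/0.050 mm at
  i = 1/3/4/9 on the LR axis). The LSTM, whose linear readout extrapolates
  affinely, is unaffected — consistent with the general observation that
  SVR handles samples unlike its training history poorly. The
  latency-ordering test is therefore expected to pass for the LSTM
  predictor and may fail for the SVR predictor on drifting sessions; this
  is a property of the method, not a defect of the implementation.
* **Hampel idempotence** holds once genuine spikes are removed; with
  thresholds pushed to the noise scale a second pass can flag further
  borderline samples (documented in `remove_outliers()`).
* Per-axis independent models: no cross-axis coupling is learned.
* The update study retrains from scratch per repeat; warm-start
  fine-tuning is available through the training API but is not part of
  the protocol.
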