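---
title: "Methods: models, simulator design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what `rehabband` computes, why each default is what
it is, and — since the package ships a simulator in place of hardware —
exactly which claims the synthetic experiments can and cannot support.

# 1. Signal model and processing chain

A wrist band holds three thin-film pressure sensors (palmar, radial,
dorsal). An analog front end low-pass filters each channel and a 12-bit ADC
samples it at 15 Hz, yielding integer AD counts in 0–4095. Four wrist
exercises are recognized; each produces a characteristic three-channel
pressure excursion that starts and ends near the wearer's resting level and
completes within 30 samples (2 s).

The chain is: **calibrate** (AD → force, offline), **normalize** (divide by
the resting reference), **gate** (find complete-action windows),
**encode** (autoencoder), **vote** (pairwise SVMs).

## 1.1 Hysteresis calibration

Thin-film sensors load and unload along different curves. `fit_piecewise()`
fits each branch with a continuous piecewise-linear least-squares model
using the hinge basis

$$ f(a) = \beta_0 + \beta_1 a + \sum_{k=1}^{K-1} \gamma_k (a-\psi_k)_+ , $$

with $K$ = `n_segments` (default 9) segments. For fixed breakpoints
$\psi_k$ this is ordinary least squares; the breakpoints themselves are
refined by iterative linearization: each iteration augments the design with
the derivative terms $-\gamma_k\,\mathbf{1}(a>\psi_k)$, solves the joint
system, and moves each breakpoint by the ratio of the two coefficients,
halving the step when the residual sum of squares does not improve. Because
this converges to a local optimum, the fit restarts from `n_starts` (default
8) seeded random breakpoint configurations plus the equally spaced one, and
keeps the best. Prediction outside the observed AD range extrapolates the
terminal segments linearly and warns.

`fit_hysteresis_pair()` fits the loading and unloading sweeps independently
and predicts force as the *average* of the two branches — the natural
estimate when the current hysteresis state is unknown. On noise-free
piecewise-linear truth with offset branches this average is recovered to
numerical precision (see `tests/testthat/test-calibration.R`), and the
reported error is $f_\mathrm{error} = f_\mathrm{predict} - f_\mathrm{true}$
with percent error undefined at $f_\mathrm{true}=0$.

Calibration is kept separate from recognition: the classifier operates on
normalized AD ratios and never needs absolute force.

## 1.2 Normalization and flattening

Band tightness differs per wearer and per donning, so the first 30 samples
of a session, taken at rest, define the reference
$\mathrm{Ref}_i$ = per-channel mean (`compute_reference()`, which rejects
non-positive references). Window samples become
$u_i(j) = \mathrm{ch}_i(j)/\mathrm{Ref}_i$, dimensionless and $\approx 1$
at rest.

A $3\times30$ window flattens channel-interleaved into 90 values:
$x(k) = u_\alpha(\beta)$ with $\alpha = ((k-1) \bmod 3)+1$,
$\beta = \lceil k/3\rceil$. In R this is exactly column-major
`as.vector()` of the $3\times30$ matrix; `unflatten_sample()` inverts it.
The index map is verified element-by-element in
`tests/testthat/test-signal.R`.

## 1.3 Pre-detection gate

Windows slide one sample at a time, so most windows hold a *partial*
action. Two rules must both pass (`is_action()`):

* **Peak rule** — the range of the oldest `prefix_len` = 10 samples exceeds
  $T_1 = 0.05$ on at least one channel: the action's onset has travelled all
  the way to the head of the queue, i.e. the action is fully inside.
* **Head–tail rule** — the *smallest* per-channel $|u(1)-u(30)|$ is below
  $T_2 = 0.03$: both endpoints sit at a common resting level, which rejects
  posture-switch ramps whose ends differ.

$T_1$ and $T_2$ are expressed in normalized ratio units. With sensor noise
of marginal SD 0.01 (Section 2), resting windows stay far below $T_1$
(0 accepts in $3\times10^4$ windows) while every generated action exceeds
it by construction. After an accepted window the detector is refractory for
one window length (30 samples), so one physical action yields one event.

A gate this simple has a designed blind spot: a ramp steep enough that its
10-sample drift approaches $T_1$ is *by construction* indistinguishable
from an action onset. The streaming tests therefore schedule posture
switches over 240 samples (drift $\le 0.017$ per prefix), the intended
"slow switch" regime; the package makes no claim about faster switches.

## 1.4 Autoencoder

`train_autoencoder()` is a plain-R implementation: 90 → `hidden_dim` (40,
tanh) → `code_dim` (10, linear) → 40 (tanh) → 90 (linear), untied mirrored
decoder, uniform fan-in initialization, Adam (step $10^{-3}$,
$\beta_1=0.9$, $\beta_2=0.999$, $\epsilon=10^{-8}$), mini-batches of 200,
mean-squared reconstruction error, 8:2 train/validation split. Every piece
of randomness (init, split, shuffling) runs under one seed and restores the
caller's RNG state, so training is bit-reproducible.

**Convergence note.** With 1000 samples and batch 200 there are only five
Adam updates per epoch, and the loss characteristically sits on a plateau
just below the raw feature variance until roughly epoch 400, then falls by
two orders of magnitude and flattens around epoch 1200–1600. The default
`epochs = 500` is therefore marginal; the package's own tests and the
acceptance script train for 1500 epochs, chosen from the loss plateau, and
`plot()` on the returned object shows both history curves so users can
check convergence themselves. A `code_dim` $\ge$ `hidden_dim` triggers a
warning since the bottleneck then does no compression.

## 1.5 One-vs-one SVM voting

`train_pairwise()` fits one linear soft-margin SVM (`e1071::svm`, C = 1, no
kernel, no rescaling) per unordered class pair on the 10-value codes — six
members for four classes. Each member is stored as an explicit hyperplane
$(w, b)$, oriented so a non-negative decision value votes for the *lower*
class index of the pair (orientation is fixed at training time by comparing
decision-value signs with predicted labels, so the convention is
independent of `e1071`'s internal label ordering). `vote()` tallies the six
votes; tallies always sum to 6 with a maximum of 3, and if one class beats
every rival pairwise it necessarily wins outright (verified exhaustively
over all $2^6$ vote patterns). Tied tallies break by the larger sum of
oriented decision values, then by the lower class index — deterministic by
construction.

## 1.6 Evaluation tools

* `confusion_matrix()` adds a fifth "none" column for actions the gate
  never released, so unrecognized actions count as false negatives.
* `compute_metrics()` reports per-class precision, recall and f1 in
  percent (flagging classes never predicted as undefined rather than
  silently imputing 0), macro averages, and the macro f1 as
  $2PR/(P+R)$ of the macro $P$ and $R$.
* `grid_search()` scans hidden/code sizes: the autoencoder is trained once
  per configuration on all data and the SVM stage is k-fold cross-validated
  on the codes (default 10-fold), reporting mean reconstruction MSE and
  classification error. Setting `leakage_free = TRUE` instead retrains the
  autoencoder inside each fold.
* `generalized_kfold()` measures *linear separability* of two code clouds:
  split each class into $k$ folds, train a linear SVM on fold $i$ of both
  classes only, test on everything else, and average the $k$ error rates.
  Well-separated clouds give $\approx 0$; identical distributions give
  $\approx 0.5$. `separability_matrix()` runs all six action pairs.

# 2. The synthetic generator

No public recordings exist for this device class, so the package simulates
them. Every design choice below is physical, made before the test suite was
run, and fixed since.

**Templates.** Each action is a deterministic $3\times30$ deviation
template built from Gaussian bumps
$A\exp\!\big(-\tfrac12((j-c)/w)^2\big)$: an early bump (centre 9, width
2.6) and a late bump (centre 23, width 2.2, amplitude $\ge 0.30$ on every
channel), with action 2 adding a mid bump (centre 15, width 3.0) for its
two-phase character. Amplitude *ratios across channels* encode which
sensors an action loads (e.g. ulnar deviation loads the radial channel
hardest). Every channel of every action carries both bumps because the
head–tail rule takes a minimum over channels: if some channel were flat,
partially entered windows could slip through the gate. Templates are
endpoint-pinned (a linear trend is subtracted so deviation is exactly 0 at
samples 1 and 30), matching the "starts and ends at rest" premise.

**Subject and trial variation.** Per-subject baselines are drawn uniformly
from 800–1600 AD counts per channel with a subject-level amplitude scale
from 0.9–1.1; each repetition gets ±20 % amplitude jitter and ±2 samples of
timing jitter (re-pinned after shifting). Raw counts are rounded to
integers and clamped to 0–4095.

**Noise.** Sensor noise is stationary AR(1) with $\rho = 0.9$ and marginal
SD 0.01 ratio units. The autocorrelation models the analog low-pass front
end ahead of a 15 Hz sampler: white noise at this SD would be physically
wrong (nothing upstream of the filter is white at the output) and would
also make 10-sample ranges occasionally exceed $T_1$, which contradicts
the premise that resting wearers produce no detections.

**Dataset acquisition mirrors deployment.** `generate_dataset()` does not
emit aligned template windows. Each training sample is produced by
embedding the action in a rest–action–rest stream and taking the *first
window the gate accepts* — exactly how the detector sees actions at run
time. Without this, gate-accepted windows at deployment are shifted 2–3
samples relative to aligned training windows, a distribution mismatch that
costs accuracy for no principled reason.

**Sessions.** `generate_session()` concatenates rest segments, actions and
linear posture-switch ramps over one continuous noise stream and returns
the stream plus exact ground-truth onsets, enabling streaming tests with
known answers.

**What the synthetic experiments show — and don't.** They show that the
implementation is *correct and coherent*: the calibration fitter recovers
known curves, the gate accepts exactly the windows it is designed to
accept, the classifier recovers the generating labels of held-out subjects
(macro-F1 100 % across every seed tried), codes are linearly separable,
and streaming equals batch processing. They do **not** show that four
real wrist exercises are recognizable at any particular accuracy: real
inter-subject variability, sensor placement, and motion artifacts are far
richer than three parameters of jitter. Synthetic recovery is a necessary
correctness bar, not a clinical performance claim.

# 3. Numerical and serialization choices

* All stochastic functions take a `seed` (< 2³¹) and restore the caller's
  RNG state afterwards; identical seeds give bit-identical results.
* Model bundles and calibrations serialize to JSON with 17 significant
  digits, the minimum that round-trips IEEE doubles exactly — a reloaded
  bundle reproduces the in-memory model bit for bit. The format stores
  layer shapes, weights, detection thresholds and the training seed, so a
  microcontroller forward pass can be re-implemented from the file alone.
* Malformed stream rows (non-finite values) are skipped with a warning by
  default; `strict = TRUE` raises a classed input error instead. All
  user-facing errors carry class `rehabband_input_error` or
  `rehabband_state_error`.
* Default problem sizes used in the package's own experiments — 5 subjects
  × 50 repetitions per action for training, 5 unseen subjects for
  evaluation, a reduced model-selection grid of hidden ∈ {10, 40, 60} ×
  code ∈ {5, 10, 25} with 5-fold CV — were chosen to run in roughly a
  minute on one CPU while leaving the qualitative conclusions (held-out
  recovery, larger hidden layers reconstruct better) clearly visible.

# 4. Parameter reference

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_segments` | 9 | — | enough segments to follow film-sensor curvature without chasing noise |
| `n_starts` | 8 | — | multistart insurance against local optima in breakpoint refinement |
| `t1` (peak) | 0.05 | ratio | ~5× the noise SD: resting ranges never reach it, action onsets always do |
| `t2` (head–tail) | 0.03 | ratio | 3× noise SD: tolerates endpoint noise, rejects differing postures |
| `window_size` | 30 | samples | 2 s at 15 Hz, the longest action duration |
| `prefix_len` | 10 | samples | first third of the window, where a complete action's onset must sit |
| `refractory` | 30 | samples | one window length: one action, one event |
| `hidden_dim` / `code_dim` | 40 / 10 | — | grid-search region of low reconstruction error with 9:1 compression |
| `epochs` | 500 | — | package default; use ~1500 for full convergence (Section 1.4) |
| `batch_size` / `lr` | 200 / 1e-3 | — | standard Adam settings; full batch when the data are smaller |
| `cost` (SVM C) | 1 | — | codes are already compact; no evidence harder margins help |
| `noise_sd` / `noise_rho` | 0.01 / 0.9 | ratio / — | film-sensor noise after the analog low-pass front end |
| `amp_jitter` / `time_jitter` | 0.2 / 2 | — / samples | trial-to-trial effort and timing variability |

# 5. Limitations

* The generator's four template shapes are stylized; nothing here
  validates recognition of *real* wrist exercises.
* The gate cannot distinguish fast posture switches from action onsets
  (Section 1.3) and assumes a stationary resting baseline; slow baseline
  drift (splint loosening) would require reference re-estimation, which
  `run_detector()` supports only via an explicit `reference` argument.
* `grid_search()`'s default (autoencoder trained on all data, CV on the
  SVM stage only) mildly favours larger models; `leakage_free = TRUE` is
  the stricter protocol.
* Hysteresis-branch averaging is the best state-free estimate but halves
  neither branch's error; a state-aware estimator would need loading
  direction as an input.
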