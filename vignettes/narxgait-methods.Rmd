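---
title: "Predicting future ankle angle and moment from EMG: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting future ankle angle and moment from EMG: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(narxgait)
```

## The problem

Active powered ankle-foot prostheses need a continuous estimate of the
*future* ankle state — sagittal ankle angle (degrees) and body-mass-normalized
ankle moment (N·m/kg) — to counteract electromechanical actuation delays on
the order of 50 ms. Surface EMG of the two antagonist lower-leg muscles
(tibialis anterior, the dorsiflexor; gastrocnemius medialis, the
plantarflexor) leads mechanical output by tens of milliseconds and carries
the user's intent, including during noncyclic episodes such as terrain
transitions. `narxgait` implements a single multiple-input multiple-output
feedforward (open-loop) NARX network that maps windows of the two EMG linear
envelopes and of the *measured* past angle/moment onto both outputs `m` time
steps ahead, together with the full training, hyperparameter-characterization
and statistical-evaluation protocol, exercised on a bundled synthetic gait
generator.

## Model

With sample period $\Delta t = 1/120$ s, prediction interval
$\tau = m\,\Delta t$ and sampling window $D = d\,\Delta t$:

$$
v_n(t+m) = \tanh\!\Big(\sum_{q=0}^{d}\sum_{i=1}^{2} a_{ni}(q)\,x_i(t-q)
\;-\; \sum_{q=1}^{d}\sum_{j=1}^{2} c_{nj}(q)\,y_j(t-q) + b_{1n}\Big),
\qquad n = 1,\dots,N
$$

$$
\hat y_j(t+m) = \sum_{n=1}^{N} w_{jn}\, v_n(t+m) + b_{2j}, \qquad j = 1,2
$$

Two asymmetries are deliberate and regression-tested: the exogenous delay
line includes the current EMG sample ($q = 0$) while the feedback line starts
at $q = 1$, and the feedback term enters with a minus sign. The network is
*open loop*: the fed-back $y_j$ are measured targets, never its own
predictions (closed-loop operation is out of scope). All fitting happens
after a per-channel min–max map of the fold's training trials onto
$[-1, 1]$, so angle and moment errors (which then span $[-2, 2]$) are
weighted equally; test data mapped outside $[-1,1]$ are passed through
unclipped, since `tanh` saturates gracefully.

## Signal conditioning

All filters are 4th-order Butterworth designs applied forward–backward
(zero phase; effective order 8), realized as cascaded biquads because the
15 Hz cutoff at a 1,200 Hz rate and the narrow 59–61 Hz notch are numerically
fragile in transfer-function form. No R package in the target environment
provides filter design, so the zpk design, bilinear transform and
second-order-section machinery live in `R/filters.R`; the responses are
checked in the tests against analytic expectations (DC gain 1, ≥ 40 dB
attenuation at 60 Hz, lag-0 peak cross-correlation for mid-passband
sinusoids, and the rectified-sine envelope level $2A/\pi$).

The EMG linear envelope chain is: 20–499.5 Hz band-pass → full-wave
rectification → 5.5 Hz low-pass → decimation ×10 (1,200 → 120 Hz), with the
small post-low-pass undershoot clipped at zero because a physical envelope is
non-negative. Kinetic channels get the 15 Hz low-pass plus the 59–61 Hz
band-stop before decimation (both cutoffs are far below the post-decimation
Nyquist of 60 Hz, so no extra anti-alias stage is needed); kinematics get the
15 Hz low-pass at 120 Hz. Forward–backward filtering uses odd-reflection edge
padding (up to 1,000 samples), long enough for the slowest design here — the
2 Hz-wide notch — to settle; edge handling changes only the first/last few
samples. Inputs with missing values are rejected: gap interpolation belongs
to the upstream motion-capture pipeline, not to this package.

Trials are truncated to the analysis window from 225 ms (27 samples) before
the first heel strike to the terminal heel strike; level walking then spans
one gait cycle, stair ascent/descent three continuous cycles (level → stairs
→ level), so terrain transitions are inside the modelled window. For
reporting, trials are linearly interpolated to per-condition common lengths
(LW 145, AS 430, DS 400 samples).

## Training protocol

Full-batch Levenberg–Marquardt on the normalized MSE, with the analytic
Jacobian of the stacked residuals (checked against finite differences).
Damping follows the classic Marquardt schedule — λ starts at $10^{-3}$,
×10 on a rejected step, ÷10 on an accepted one — since the source method
names the algorithm but no schedule. Accepted steps never increase the
training loss; a stall (no damping value yields descent) is reported as a
patience stop. Windows never cross trial boundaries ("a concurrent set of
sequences"), which avoids the artificial discontinuities that single-sequence
concatenation would inject.

The trial-blocked protocol holds out one novel test trial per condition per
fold; the remaining trials are shuffled once per fold and split into
contiguous blocks of 8 training and 2 validation trials per condition.
Stopping is by error goal, validation patience (default 6 epochs), or an
epoch cap, and the returned weights are those of the best validation epoch.
Ten restarts from different seeded initializations (uniform
$\pm\sqrt{3/\mathrm{fan\_in}}$, a standard scale the source does not specify)
are trained per fold, and the restart with the lowest normalized MSE averaged
across the three ambulation conditions on the fold's train + validation data
is selected — train + validation rather than validation-only, because the
subset is not stated in the source and the novel test trial must stay
untouched until evaluation. The characterization phase uses an error goal of
1% of the pooled normalized moment variance of the fold's recorded
(train + validation) trials; whether the original computed that variance in
physical or normalized units is not stated, and normalized was chosen
because it is the space of the training loss. The finalization phase re-trains
at error goal zero.

## Hyperparameter characterization

The protocol grid is τ ∈ {33, 42, 50, 58, 67, 75, 83, 108, 142} ms,
D ∈ {8, 17, 33, 50, 67, 83} ms, N ∈ {2, …, 16} (432 cells); milliseconds
convert to steps by nearest-integer rounding with a floor of one step (58 ms
↔ 7 steps; 8 ms → 1 step). Marginal RMSE curves collapse the tensor by
averaging over the two non-selected axes; each marginal gets an OLS fit with
an F-test for zero slope. At the fixed 58 ms prediction interval, the optimal
(D, N) is the argmin of held-out normalized MSE averaged over conditions,
outputs and folds, ties broken toward smaller N then smaller D (cheaper
networks at equal error; the source reports no ties). The desk-scale default
is the reduced grid (τ {33, 58, 142} × D {8, 33, 83} × N {2, 6, 12}) with 3
folds, 2 sweep restarts and 3 finalization restarts — a full 432-cell,
10-fold, 10-restart sweep is hours of CPU, not minutes — and every cell
records the seed that produced it, so sweeps are deterministic and resumable.
The number of folds feeding the sweep is exposed as a parameter because the
source does not state it.

## Evaluation

Per held-out trial and output: RMSE in physical units, and R² obtained by
squaring the peak of the normalized cross-correlation. Correlation is
computed as Pearson-at-lag on the overlapping segments with per-lag
re-centering (raw sliding dot products conflate offset and shape), the lag
search is bounded at ±25% of trial length, and the peak is taken on
|correlation| before squaring — "squaring the peak" is sign-ambiguous, so the
magnitude peak's lag is what gets reported. Instantaneous RMSE across trials
is computed on the common-length time base; its ±1 SD band is the SD across
trials of squared errors propagated to the RMSE scale (delta method). Both
within-fold and pooled aggregations are labelled in the report, since the
original's averaging order across trials and participants is not fully
specified.

EMG contribution is probed by the constant-EMG ablation: each test-trial EMG
channel is replaced by its own temporal mean (same average signal power, no
time-varying information) and the trained network is re-run. On the
EMG-coupled synthetic benchmark this must *fail* the operating-point error
bounds that the time-varying-EMG model meets.

Critical performance points: stance events (toe-off, maximum dorsiflexion,
maximum plantarflexion, maximum plantarflexion moment) are located on the
target series and sampled on both series at that index; clearance intervals
take every sample in a fractional-time band. Sign conventions are recorded in
every report: dorsiflexion-positive angle (maximum plantarflexion = angle
minimum) and plantarflexion-positive moment (the push-off peak is the moment
maximum). Paired differences are gated by Shapiro–Wilk at α = 0.05 into a
paired t-test or an exact binomial sign test — Shapiro–Wilk alone is the
gate; skewness is not a second criterion — with all-zero differences reported
as "identical" (p = 1) and zero-variance non-zero differences sent to the
sign test. p-values are Benjamini–Hochberg adjusted at FDR 0.05 (step-up with
enforced monotonicity). Clearance-interval timings are configuration inputs
(the real staircase geometry they derive from is not reconstructible); the
synthetic defaults sit at the swing-phase angle minimum of the template's
middle cycle ± 3% of the trial.

## The synthetic generator: what it emulates, and what it does not

The source study's raw data are not deposited, so the package ships a seeded
generator whose templates are hand-built Gaussian-bump approximations of
normative gait curves: dorsiflexor bursts around heel strike and in swing, a
plantarflexor burst into push-off, level-walking angle in roughly
[−17°, +11°] with stair-descent amplitudes 1.3× level walking (stair descent
has the widest range of motion), and a single dominant plantarflexion moment
peak (≈1.4 N·m/kg) per stance. Cycle lengths are 120/143/132 samples
(LW/AS/DS) so the truncated trials (148/457/424 samples) sit near the
reported common lengths. These magnitudes are normative, not fitted to any
dataset.

Trial-to-trial variability has four parts, each seeded per
(seed, condition, trial index) so trials are independent and reorderable:

* **amplitude jitter** — lognormal per-trial gains (SD 0.10 of log), per EMG
  bump and channel; mechanical channels get half that SD because their
  trial-specific deviations are meant to come through the EMG coupling;
* **time warp** — the cumulative integral of a positive jittered rate
  (log-SD 0.015), renormalized so endpoints are pinned: the phase axis is
  guaranteed monotone and events move with it;
* **activation jitter** — a smooth (≤ 3.5 Hz) multiplicative fluctuation
  (SD 0.18) of the EMG envelopes within the trial: the information-bearing
  component;
* **additive measurement noise** — smooth, small (EMG 0.004, angle 0.08°,
  moment 0.0035 N·m/kg).

With `emg_coupling` > 0, the deviation of the observed activation from the
warped *condition template* is passed through a causal lag-and-smooth
operator (100 ms delay + one-pole 6 Hz low-pass — EMG leads mechanics by
clearly more than the 58 ms prediction interval) and added to angle and
moment with fixed gains (angle +18/−13.5 degrees, moment +1.2/−0.25 N·m/kg
per unit envelope, TA/GM appropriately signed). Referencing the condition
template rather than the trial's own gain-jittered base means amplitude
jitter propagates to mechanics as well: every trial-specific feature the
network can see in the EMG is mechanically meaningful, rather than an
irreducible mix of inert and informative deviations. Constant-EMG inputs
therefore destroy exactly the information this pathway carries. With all SDs zero the generator
reproduces the template bit-exactly regardless of coupling — the noise-free
contract the tests assert. Simulated raw EMG (a 20–450 Hz band-limited noise
carrier, unit mean absolute amplitude, modulated by the envelope) lets the
envelope chain be tested end to end.

The noise magnitudes are artifact choices — the source reports no
quantitative trial-variability statistics — and were calibrated **once**, as
the acceptance protocol prescribes, so that the time-varying-EMG model meets
the benchmark operating point (angle RMSE < 1°, moment RMSE < 0.04 N·m/kg,
R² > 0.99 at τ = 58 ms) while the constant-EMG ablation fails those bounds;
they were then frozen. A green benchmark therefore establishes that the full
pipeline — generation, preprocessing, trial-blocked training, selection,
evaluation — reproduces the *operating claims* on data with the stated
morphology and an EMG-borne information pathway. It does not establish
performance on real gait: real EMG has heavier-tailed, nonstationary noise,
cross-talk and electrode artifacts; real kinematic variability is not a
smooth warp; and inter-subject variation is absent entirely.

## Numerical choices and degenerate inputs

* ms→steps: nearest integer, floor 1 (reproduces the printed 58 ms ↔ 7 steps
  and maps the 8 ms window to one step).
* Min–max maps reject constant channels; round-trip apply→invert is exact to
  < 1e−12 and serialization uses 17 significant digits so model JSON
  round-trips bit-exactly.
* `teacher_generate` needs d + m initial target rows (the forward equations
  for index s reach back to s − m − d), a detail visible already at
  d = m = 1.
* LM: singular normal equations raise damping rather than failing; λ is
  capped at 1e12, after which the epoch counts as a stall.
* Cross-correlation ties between lags break toward the smallest |lag|;
  constant series raise an error rather than returning NaN.
* Trials shorter than d + m + 1 samples are rejected with a length error;
  a trial of exactly d + m + 1 yields one prediction.

## Known limitations

One qualitative claim of the source method does **not** hold on the
synthetic world: the sampling-window (D) marginal of the sweep is not flat
relative to the prediction-interval (τ) marginal. At D = 8 ms the feedback
window is a single past target sample — no velocity information — and the
generator's time warp makes a cyclic trajectory phase-ambiguous from
position alone, so the 1-tap cells are structurally much worse (angle RMSE
≈ 1.5° vs ≈ 0.44° at d = 4, even with heavy training). Real gait data
evidently lack this ambiguity. The corresponding acceptance check is left
failing rather than re-tuning the generator after observing the outcome;
the τ-trend (RMSE rising with τ) and the N-flatness both hold.

Closed-loop (prediction-fed-back) operation, gait-event detection from force
thresholds, marker processing and inverse dynamics are out of scope — the
package consumes angle/moment series as given. The desk-scale defaults trade
statistical resolution for runtime; protocol-scale runs are supported but
slow. Participant-level (mixed-effects) inference is not implemented: the
synthetic benchmark has no participants, only trials.
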