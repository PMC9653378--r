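---
title: "Models and methods: two-finger velocity decoding from spike-band power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: two-finger velocity decoding from spike-band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingerbmi)
```

# The problem

An intracortical brain-machine interface for finger control converts binned
neural features into velocity commands for two independently controlled
finger groups. The neural feature throughout this package is spike-band
power (SBP): the time-averaged magnitude of the 300-1000 Hz band of each
electrode's signal in 50-ms bins, a proxy for nearby single-unit firing.
Positions live in normalized units u in [0, 1] per finger (0 = full
extension, 1 = full flexion; the package fixes this convention once — the
math is convention-independent), velocities in u/s, and every clock in the
system ticks at dt = 0.05 s.

The package implements two decoder families over this interface — a
position-velocity Kalman filter with recalibrated feedback intention
training (ReFIT), and a shallow feed-forward neural network with a learned
time-feature layer and its own ReFIT pass — together with everything needed
to exercise them without animal data: a synthetic cortical encoder, an
intention-driven task simulator, a closed-loop (brain-control) engine, and
Fitts's-law performance assessment.

# The Kalman filter

The state is `x_t = (P1, P2, V1, V2, 1)`; the trailing 1 carries the
baseline offset. The transition matrix fixes the physical rows
(`P_t = P_{t-1} + dt V_{t-1}`) and learns only the 2x2 velocity block,
cross-terms included. The observation map `C` is a least-squares regression
of SBP at bin `t` on the state at `t - lag` (the physiological lag, one
50-ms bin under the default encoder); `W` and `Q` are residual covariances.
A time-lagged-feature variant (`n_feature_lags = 3`) stacks bins
`t, t-1, t-2` into one augmented observation, giving the filter the same
input window as the network.

Two conventions matter:

* **Gain without position uncertainty.** The ReFIT-style decoder zeroes
  the position (and offset) rows/columns of the a-priori covariance each
  predict step, so the Kalman gain routes innovations into the velocities
  only and decoded position *exactly* integrates decoded velocity (the
  `1e-12` contract tested in the suite).
* **Velocity-only observation columns.** By default the position columns
  are dropped from the `C` regression (`drop_position = TRUE`). With
  position columns present and a gain that carries no position
  uncertainty, the position-innovation feedback loop
  `P -> innovation -> V -> P` has spectral radius above 1 for a
  substantial fraction of synthetic encoders — the decode drifts. We
  measured this directly (and it degrades even noiseless self-decodes);
  dropping the position columns removes the loop and makes the noiseless
  self-decode exact. Full-state fitting remains available and is used by
  the recovery tests; the classic restricted-range filters (below) keep
  the full state because their gain carries position uncertainty and is
  stable.

**Steady-state form.** Once the gain converges (checked against a
fixed-point tolerance of 1e-12), the velocity update can be written as a
weighted sum of the previous estimate and the current neural estimate,
`V_t ~ alpha V_{t-1} + (1 - alpha) beta D y_t`. The stored object keeps the
exact operators `(I - K_ss C) A` and `K_ss`, so the steady-state decode
reproduces the recursive decode to better than 1e-6 per bin after a
200-bin burn-in — the reconstruction contract is what defines the
extraction, not any particular formula. The scalar summaries are
`alpha` = mean diagonal of the velocity block of `(I - K_ss C) A` and a
`beta`/`D` split of the velocity gain rows normalized to unit mean column
norm. Online tuning multiplies `alpha` by 1.25 (clipped below 1) and
`beta` by 1.2: the history operator is scaled by `alpha'/alpha` and the
neural-input side by `beta_scale (1 - alpha')/(1 - alpha)`, which reduces
exactly to the scalar rule. Positions never receive gain or smoothing.

**ReFIT.** After a closed-loop block, the decoded velocities are
re-oriented toward the known targets — either rotated (magnitude
preserved, direction along the per-finger distance vector; on-target bins
map to zero velocity) or sign-flipped per finger (zeros never flipped) —
and the filter is refit on the corrected kinematics. Rotation conserves
speed to 1e-12 and flipping is idempotent; both are property-tested.

**Restricted-range filters.** `fit_restricted_kalman()` trains a classic
filter (full state, position uncertainty, learnable velocity block) only
on bins where both fingers' velocities exceed `-sigma/2` (positive side)
or fall below `+sigma/2` (negative side), with sigma the per-finger
standard deviation over the session. A bin qualifies only if both fingers
qualify. These fits show that a linear read-out trained within one
movement context reaches higher speeds in that context than a full-range
compromise fit.

# The neural network

The reference network takes the 3 most recent 50-ms bins per electrode. A
time-feature layer — one linear map from 3 bins to 16 features, shared
across electrodes, followed by batch normalization over the 16 feature
channels and a rectifier — is flattened to `16 E` inputs (1536 at 96
electrodes) and feeds 4 fully connected layers (hidden width 256; order
linear, dropout 0.5, batch norm, ReLU; final layer linear with 2 outputs).
At 96 electrodes the network has 527,202 learnable parameters (batch-norm
scales/shifts included), which rounds to 5e5.

Training minimizes mean-squared error with Adam on mini-batches of 64 time
steps (each carrying its 150-ms history). "Momentum 0.9" is read as Adam's
first-moment decay (`beta1 = 0.9`, `beta2 = 0.999`); weight decay is
coupled L2 added to every gradient, matching the optimizer named for the
original implementation. Training targets are z-scored per finger; this is
the reading we adopt of the output normalization (the alternative "twenty
times the peak magnitude" phrasing is descriptive, not a constraint — the
gain step below restores physical units either way). Targets can be
resampled so the pooled velocity distribution is triangular on
[-4 sigma, 4 sigma] (importance resampling; per-bin weight = product of
the two fingers' target/empirical density ratios, which converges to the
target distribution for near-independent fingers — a mean of ratios
provably does not; the empirical densities are equal-width histograms,
whose per-bin estimates do not inherit kernel-smoothing bias at the
triangular peak). Kaiming initialization, zero biases.

After training, an unlearned **gain factor** maps raw outputs to physical
scale: gain = mean magnitude of actual-velocity peaks / mean magnitude of
predicted peaks on the validation set, where a peak is a local maximum of
|v| above one standard deviation of the series with at least 250 ms
separation (the peak rule is ours; no sharper definition exists upstream).
Any nonzero median of the gain-scaled predictions is subtracted. The
prediction path is deterministic: dropout off, batch norm on running
statistics; the first two bins of a session replicate the earliest bin as
history.

**ReFIT-NN** builds its truth signal from the decoder's own closed-loop
output by flipping each finger's velocity whenever it pointed away from
the target, then continues Adam from the existing weights for 500
iterations (fresh optimizer moments; batch-norm running statistics keep
updating). The gain is recomputed on the retraining run by default;
scaling the previous gain by 0.75 is supported as the alternative.

**Nodal contributions.** Because the last hidden layer is rectified, node
`k` contributes `N_k W[k, f]` of a single sign to finger `f`; nodes are
classed positive/negative by `sign(W[k, f])` and their mean contributions
are summarized in three true-velocity regimes (v > sigma, v < -sigma,
|v| < sigma/4). The decomposition `sum_k N_k W[k, f] + bias_f` equals the
raw output exactly and is asserted to 1e-5.

# The synthetic world

The generator emulates the statistical structure the decoders assume, not
any particular animal.

**Encoder.** Each channel's expected SBP is
`baseline + w_p . P + (1 - mix) w_v . V + mix w_rect . sat(V+, V-)` on
kinematics `lag_bins` in the past, plus Gaussian noise, clipped at zero.
The rectified features pass through a per-channel saturation
`s tanh(x / s)` with `s ~ U(0.3, 0.9)` u/s. The rectified weights are
dominated by unsigned *speed* tuning: each channel draws a magnitude
`m ~ +/-U(0.2, 0.6)` and a directional asymmetry `d ~ U(-0.4, 0.4)`, so
`w+ = m(1 + d)`, `w- = m(1 - d)`. These two choices are what make the
world genuinely nonlinear for a linear read-out: purely rectified tuning
is a red herring (`max(v,0) - max(-v,0) = v`, so a population with
independent sign weights is *exactly* linearly invertible and a Kalman
filter loses nothing), whereas unsigned speed components are uncorrelated
with signed velocity and saturation bounds what any linear combination
can reconstruct at high speed. Both are well-documented features of motor
cortex. Weight ranges are bounded and baselines drawn from U(4, 6) so the
noiseless expectation can never clip — this is what makes exact
linear-recovery contracts (1e-6) attainable for every seed. Dead channels
emit noise only.

**Simulated user.** Intended velocity is `clip(g (target - P), +/-v_max)`
with g = 3 /s and v_max = 1.5 u/s, smoothed by a one-pole filter
(tau = 150 ms), perceived with a 150-ms reaction delay, and jittered by a
multiplicative log-normal factor (sd 0.15). The delayed-loop gain
`g (delay + tau) ~ 0.9` stays below pi/2, so the user settles instead of
oscillating — open-loop trials always succeed and speed profiles are
bell-shaped. An optional additive per-bin motor tremor (`tremor_sd`,
default off) is available for studying less predictable intention
signals. All randomness flows from one session seed through named streams
(targets, user, encoder noise), which is why a closed-loop run with the
oracle decoder is bin-for-bin identical to an open-loop simulation of the
same seed.

**Task.** Random target pairs uniform over the placement range (100% of
the range in training, 95% online), rejected until |t1 - t2| <= 0.5 and
neither target interval overlaps the previous trial's; hold 750 ms in
training and 500 ms in testing, dwell reset on target exit (continuous
hold); trial timeout 10 s (no value exists upstream; it is configurable).
The trial record keeps the initial centre-to-target distances `D_k` used
by the throughput formula `sum_k log2(1 + (D_k - S)/(2S)) / t_acq` with
S = half the target width.

**What the generator does not emulate:** electrode degradation and
day-to-day nonstationarity, correlated or heavy-tailed noise,
within-session tuning drift, reaction to reward, or any learning by the
user. Passing the suite therefore shows the algorithms are implemented
correctly and behave as reported *in a world satisfying their
assumptions*; it is not evidence about any particular animal's data.

# Study conditions and problem sizes

The simulation studies in the test suite fix their conditions once:
64-channel encoder, nonlinearity mix 0.8, lag one bin, noise sd 0.35 —
chosen so that single-channel velocity correlations land in the 0.2-0.4
range typical of good M1 channels and population decodes land near the
reported mid-0.x correlations. Offline ablations use 400 training / 100
validation trials and five seeds. Network training in the studies runs
1000 Adam iterations at a step size of 5e-4 with weight decay 2e-3: the
upstream recipe (1e-4 with decay 1e-2 over 3500+ iterations) sees ~4x
more samples, so the step size is scaled up and the decay down to keep
the total amount of learning and of shrinkage comparable at the reduced
iteration count — with the original decay at the larger step, the
adaptive L2 visibly erodes the weights past ~600 iterations. The
closed-loop ReFIT study trains on 200 open-loop trials, calibrates each
decoder on a 100-trial brain-control block, refits, and evaluates each of
KF, ReFIT-KF, NN and ReFIT-NN on 100 fresh trials per seed.

# Numerical choices and degenerate inputs

* Innovation covariances are inverted by Cholesky/LU with a Moore-Penrose
  fallback, so noiseless (singular-Q) sessions decode exactly rather than
  erroring.
* The gain recursion freezes once `||K_t - K_{t-1}||_inf < 1e-13`; the
  steady-state extraction errors if no fixed point is reached.
* Lag estimation breaks ties toward the smaller lag.
* Rotation on an exactly-on-target bin returns zero velocity; flipping
  never flips a zero.
* The band-pass front end is a 4th-order Butterworth applied forward and
  backward (zero phase, so it introduces no lag of its own); trailing
  partial bins are dropped, never padded; sampling rates must be integer
  multiples of 2 kHz.
* Batch normalization uses eps 1e-5 and running-statistic momentum 0.1;
  a fully dropped-out unit normalizes to its shift parameter.
* Redistribution floors the histogram density estimate at 1% of the
  uniform density over [-4 sigma, 4 sigma] to bound importance weights;
  the scale of the triangular target defaults to the pooled velocity
  standard deviation and can be supplied explicitly.
* CSV payloads are written with 17 significant digits, so session and
  model archives round-trip bit-for-bit; model archives carry an
  order-sensitive checksum verified on load.

# Known limitations

The closed-loop user is a proportional controller, not a learning agent:
it cannot reproduce practice effects or co-adaptation, which upstream
reports suggest matter for linear decoders. The ReFIT benefit in this
stationary world comes only from closed-loop distribution shift and
intention correction, so it is smaller and noisier than with a real,
adapting user; the suite accordingly asserts only its direction.
Correlation comparisons give the Kalman filter credit for its one-bin
display delay (decodes are aligned at the physiological lag); the network
is evaluated unaligned, matching how each decoder is used online.
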