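---
title: "Decoding handwriting from neural signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding handwriting from neural signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handbci)
```

This vignette is the package's own account of its models: what is computed,
which choices were open and how they were resolved, what the synthetic data
emulates, and what the tests do and do not demonstrate about real
recordings.

## 1. The decoding problem

A trajectory-based handwriting BCI fits multichannel neural features to the
2-D pen velocity of an attempted writing movement, integrates velocity into
a trajectory, and recognizes the trajectory as text. The central
methodological problem the package addresses is *label misalignment*: the
subject's executed timing differs, non-uniformly within a trial, from the
prompted timing that serves as the training label. A mean-squared-error
(MSE) loss scores predictions by one-to-one temporal matching and therefore
penalizes a decoder that writes the right shape at the executed timing; the
DILATE loss scores shape and timing separately and differentiably.

## 2. Alignment core

For sequences $y$ ($m$ samples) and $z$ ($n$ samples) the cost matrix is
$\Delta_{ij} = \lVert y_i - z_j\rVert^2$. Admissible alignment paths run
from $(1,1)$ to $(m,n)$ with unit steps right, down, or diagonally.

* **DTW** minimizes $\langle A, \Delta\rangle$ over admissible paths by the
  standard dynamic program. Backtracking prefers diagonal, then vertical,
  then horizontal moves, so optimal paths are deterministic under ties and
  alignment offsets stay minimal.
* **soft-DTW** replaces the minimum with
  $\mathrm{softmin}_\gamma(a) = -\gamma\log\sum_i e^{-a_i/\gamma}$,
  evaluated with a max-shift so that $\gamma$ as small as $10^{-4}$ against
  costs of order $10^3$ neither overflows nor underflows. The dynamic
  program runs in cost space, never in probability space.
* **The relaxed optimal path** $A^*_\gamma = \nabla_\Delta
  \mathrm{softDTW}_\gamma$ is the expected path matrix under the Gibbs
  distribution over paths; it is computed by the soft-DTW backward pass.
* **soft-TDI** is $\langle A^*_\gamma, \Omega\rangle$ with
  $\Omega(i,j) = (i-j)^2$, optionally (and by default) divided by $mn$.
  Its gradient with respect to $\Delta$ is a Hessian-vector product of
  soft-DTW, computed by forward-mode differentiation through both
  recursions (an $O(mn)$ pass, implemented in C++ alongside the other
  kernels).
* **DILATE** is $\alpha\,\mathrm{softDTW} + (1-\alpha)\,\mathrm{softTDI}$,
  defaults $\alpha = 0.5$, $\gamma = 0.001$. `dilate_grad()` chains
  $\partial\Delta/\partial z$ through both terms, giving the analytic
  gradient used by every trainer in the package.

Open design points and their resolutions:

* *Time-penalty normalization.* The plain $(i-j)^2$ penalty grows like
  $n^2$ while the shape term grows like $n$; dividing by $mn$ keeps the two
  terms on comparable scales so that $\alpha = 0.5$ weights them
  meaningfully across sequence lengths. Both variants are available
  (`normalize` argument); the normalized form is the default everywhere.
* *fastDTW.* Coarse-to-fine projection with a configurable radius (default
  1; recognition uses 2). The restricted search guarantees
  `fast_dtw >= dtw`; the suite checks equality on smooth fixtures.
* Exact DTW supports unequal lengths and imposes no window.

The whole core is validated against brute-force path enumeration for all
sequence lengths up to 5 and against central finite differences for both
gradient passes.

## 3. Handwriting kinematics

Glyphs are ordered polyline segments labelled stroke or pen lift, with pen
lifts synthesized as straight movement segments exactly like strokes.
Writing speed is constant across the glyph: each *straight piece* (every
polyline edge) receives a duration proportional to its length and a
triangular ("bang-bang") velocity profile $v(t) = at$ then $aT - at$, with
$a = 4L/T^2$ solved so the profile integrates to the piece's displacement.
Applying the profile per straight piece rather than per multi-corner stroke
matters: a corner must pass through a speed minimum, which is what gives
each character its distinctive multi-lobed speed profile — the signature
the recognizer relies on.

Sampling is left-closed at 20 Hz ($t = k/f_s$), followed by 5-point centred
moving-average smoothing with replicated edges (the smoothing window is a
modelling choice; edge handling is unstated in the source description and
replication preserves displacement best). Total duration defaults to 4 s at
arclength $\le 1$ and 8 s at arclength $\ge 5$, linear in between — glyph
units are the unit square, so typical letters land at 5–7 s, matching
guided-writing pacing. Positions are cumulative sums of velocity over the
sample period; `differentiate_position()` inverts that convention exactly.

Coordinates are x-rightward, y-upward in $[0,1]^2$; screen-down sources
must be flipped at import. Glyph templates serialize to JSON (canonical)
or flat CSV, both validated for segment connectivity on read.

## 4. Neural features

All recipes follow the standard cascades literally (order asserted by
tests): ESA (300 Hz first-order Butterworth high-pass, rectify, 12 Hz
first-order low-pass, 1 kHz), SBP (300–1000 Hz second-order band-pass,
rectify, 2 kHz), LFP (500 Hz low-pass, 2 kHz, $\pm 3$ SD clipping,
third-order low-pass), five LFP band powers (1–4, 3–10, 12–23, 27–38,
50–300 Hz; squared band-filtered amplitude), LMP (50 ms non-overlapping
means of the LFP), threshold crossings (250–5000 Hz band-pass, negative
crossings of $-k\times$ rms with 1 ms lockout, $k = 4.5$ or $6.25$), and
cMUA (300–6000 Hz band-pass, square, 100 Hz low-pass, clip, square root,
1 kHz).

Choices where the recipes are silent: filtering is zero-phase
(forward–backward) for offline parity, with a causal flag for
pseudo-online use; the unstated cutoff of the post-clipping LFP low-pass is
500 Hz (continuing the anti-alias intent); down-sampling decimates after
each recipe's own final low-pass; rms for threshold detection is computed
per channel over the whole segment.

Binning: feature bin $t$ aggregates the stream over the 200 ms window
ending 300 ms *before* kinematic sample $t$ on a 50 ms grid — i.e. neural
activity leads the kinematics it encodes, and a stream impulse surfaces in
kinematic bins 300–500 ms later. Continuous features are averaged per bin;
threshold-crossing counts are summed. The raw-recording simulator leads the
kinematics by `lag + bin/2` = 400 ms so that its spike rates align with the
binned grid. Channel z-scoring freezes training-fold statistics for test
data; noise augmentation adds per-channel Gaussian noise at 0.2–1.0 times
the channel SD.

## 5. Decoders

* **Kalman filter**: state = 2-D velocity plus a constant-1 bias channel;
  $A$ and $H$ fitted by least squares over stacked training pairs (ridge
  fallback with a warning when the regressors are rank-deficient), $Q$, $R$
  as residual covariances, $B = 0$. Decoding runs the standard
  predict/gain/update recursion from a zero state with $P_0 = I$; a
  singular innovation covariance falls back to the pseudo-inverse. The
  one-step update is pinned against a hand-computed scalar recursion at
  $10^{-12}$.
* **LSTM sequence decoder**: one 512-unit layer (Glorot-uniform
  initialization, forget-gate bias 1) with an ELU readout into an affine
  map to 2-D velocity; batch size 1, dropout 0, learning rate 0.001.
  Backpropagation through time is hand-written and verified against finite
  differences for both losses. Under DILATE, output and label are z-scored
  per dimension before the loss (the fitting convention for neural data,
  where the initial output scale is arbitrary) and the z-score transform is
  differentiated exactly.
* **Linear decoder**: the single linear layer used by the simulation
  experiments, trained the same way. The simulations apply DILATE to *raw*
  velocities — z-scoring there would erase the very scale/offset dependence
  the toy landscape studies.
* **Optimizer**: the source states learning rate, batch size and dropout
  but not the optimizer or epoch count; the package uses adaptive-moment
  gradient descent (Adam), default 100 epochs with early stopping on a
  10-epoch plateau, returning the best-loss parameters. The simulation
  trainers use a 40-epoch plateau window with step halving, because
  per-trial updates under the near-hard soft-min ($\gamma = 0.001$) are
  noisy and a short patience systematically under-trains the DILATE
  decoder. One master seed fans out deterministic per-fold seeds.
* **Cross-validation** is leave-one-character-out: every repetition of the
  held-out character leaves the training set (audited by id); with 30
  characters and 3 repetitions each fold trains on exactly 87 trials.

Position decoding (direct regression to position rather than velocity
integration) is available by passing positions as targets; the decoders are
agnostic to which kinematic quantity they fit.

## 6. Recognition

The template library stores per-dimension z-scored velocity profiles of
synthesized glyphs. A query is z-scored and matched by fastDTW distance
(radius 2; exact DTW serves as the oracle in tests) or by Pearson
correlation after linearly resampling both sequences to the query length
(the correlation convention for unequal lengths is a package choice; plain,
not lagged, correlation is used). Ties break lexicographically.
Recognition-rate curves subsample the library at each size, always forcing
the experiment characters into the subsample; at the experiment size and
the full size the subsample is forced entirely, so the SD is zero there by
construction. Comparisons happen in velocity space, not position space.

## 7. Simulation experiments

* **Timeline resampling** draws $n$ uniform times over a trajectory's time
  range, sorts them (clamping the final draw to the range end so the
  endpoint is preserved), reads positions off the space-time polyline, and
  differentiates. The resampled points lie exactly on the original path:
  shape is preserved, timing is distorted — mid-trial offsets of roughly
  $\pm 250$ ms at typical glyph durations.
* **Toy landscape**: label $y$ = 100 zeros with a triangular bump
  (10, 25, 30, 25, 10 at samples 31–35; mean 1), input $x$ = the same bump
  delayed 8 samples, prediction $ax + b$ over $a \in [-2,2]$,
  $b \in [-1,2]$, step 0.1. The reference waveform is a package-defined
  surrogate consistent with the described setup (the original figure data
  are unavailable); its mean-1 baseline makes the least-squares optimum
  round to $(0,1)$ on the grid while the shape-preserving identity $(1,0)$
  minimizes DILATE. No z-scoring is applied inside these losses. The MSE
  surface is validated against the closed-form least-squares solution.
* **Misalignment experiment**: 26-glyph corpus, 3 repetitions per glyph
  (independent resamplings), a frozen 96-channel linear encoder (weights
  $\mathcal N(0, 1/2)$), observation noise with per-channel SD equal to the
  channel's signal SD (channel-level SNR of one, typical of single-trial
  intracortical features), 5-fold character-level cross-validation of the
  linear decoder under each loss, and DTW-template recognition of the
  decoded trajectories. Metrics are reported against the *executed*
  velocity.
* **Multi-day fusion**: day 1 uses the letter corpus; each later day
  contributes as many new random glyphs (unique characters per day), all
  resampled per trial through the same encoder with per-day drift
  (lognormal gain, sdlog 0.1; additive offset at 0.1 channel SD). Features
  are z-scored per day per channel before pooling; the day-1 test folds
  never change. Training sets of different sizes receive an equal
  optimization budget (a minimum number of per-trial updates) so that
  day-count comparisons are not confounded by under-training.

### What the measured outcomes show — and what they do not

The directional results the suite asserts: DILATE reconstructs label shape
better than MSE under misalignment (lower normalized DTW), DILATE does not
degrade as days of misaligned data are added, the aligned control is easy
for MSE, and warping a decoded trajectory onto the reference can only
improve its correlation to the label.

Two directional claims from the source study do *not* reproduce under this
package's conditions, deliberately left as failing acceptance checks rather
than adjusted: (1) a large (≥ 20-point) DTW-recognition gap between DILATE
and MSE under misalignment, and (2) a decline in MSE similarity as days are
added. The structural reason is instructive: an instantaneous linear
decoder's MSE optimum is a fixed $2\times 2$ map of the executed velocity —
it shrinks and mixes axes but cannot smear time, so its output remains a
shape-preserved warp of the prompt, which a warp-tolerant DTW recognizer
identifies at ceiling. The original gap was measured with a brittle
external handwriting recognizer that this package intentionally replaces
with DTW template matching. On real recordings, with nonlinear encoding,
recurrent decoders and genuine neural noise, the gap can re-emerge; the
simulations here bound what synthetic linear sessions can show.

## 8. Synthetic data

The generators emulate the *structure* of the study's data: block-capital
stroke templates (1–4 strokes, at least five distinct segment counts across
the corpus), sessions of characters × repetitions, linear velocity encoding
with drift and noise, and 30 kHz raw recordings with velocity-tuned
inhomogeneous point-process spiking (2 ms refractory period), biphasic
1.2 ms waveforms at a chosen SNR over a pink-plus-white background. They do
not emulate: nonlinear or history-dependent neural encoding, electrode
instability within a session, artifacts beyond what $\pm 3$ SD clipping
addresses, or the stroke statistics of real scripts. Tests passing on this
synthetic data certify the implementation, not clinical performance.

Problem sizes used by the heavier checks (chosen to keep the full suite in
the tens of minutes on one CPU): misalignment and multi-day experiments run
with 2 repetitions per glyph, the multi-day comparison evaluates day counts
1 and 6, and raw-recording fixtures use 3 channels × ~3 s.

## 9. Orchestration and formats

Experiment configs are flat JSON; every pipeline run writes per-trial
metrics as CSV plus an atomically-renamed JSON manifest carrying the config,
its hash, the master seed, the package version and summary metrics, so any
archived run can be reproduced bit-for-bit. Signals, features and models
live in plain-text containers (JSON/CSV) rather than a binary array format:
the data volumes at this scale do not warrant one, and text keeps runs
diffable and archivable; the serializers are documented interfaces, so a
binary backend could be swapped in without touching the module surfaces.

## 10. Known limitations

* The LSTM trainer is pure R; at the published scale (512 units, 96
  channels, hundreds of trials) training is slow. The linear decoder is the
  practical engine for simulation-scale work, exactly as in the source
  study's simulations.
* `fast_dtw` is exact on smooth inputs at small radii but is an upper
  bound in general; recognition inherits that approximation (radius 2).
* The Kalman observation model is linear-Gaussian; it is the baseline, not
  the recommended decoder, and underperforms the recurrent decoder on
  curved trajectories.
* Offsets statistics (`alignment_offsets`) report both the signed mean and
  the mean of absolute offsets, since the source is ambiguous about which
  enters the per-trial summary; the SD is always of absolute offsets.
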