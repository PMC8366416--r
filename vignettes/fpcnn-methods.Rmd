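---
title: "Methods: the force-pattern network and its validation pipeline"
author: "fpcnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the force-pattern network and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fpcnn)
```

This vignette documents the science behind `fpcnn`: the decoding model
and its assumptions, the preprocessing chain, the synthetic data the
package validates itself on, and every numerical design choice that was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Problem setting

Surface EMG (sEMG) over the forearm carries enough information to
reconstruct continuous wrist and hand kinematics, which is the basis of
regression-style ("proportional") myoelectric control of prosthetic
hands. The package decodes three degrees of freedom from a 32-channel
electrode sleeve: wrist flexion/extension (WF/WE), forearm
pronation/supination (P/S), and hand grip/open (HG/HO). By convention
WF, P and HG are positive angles and WE, S and HO negative; the neutral
posture (central position, CP) is 0° on all joints. The sleeve carries
two 4 × 4 electrode grids — a flexor face (channels 5–8, 13–16, 21–24,
29–32, one row per group) and an extensor face (1–4, 9–12, 17–20,
25–28). Raw EMG is sampled at 500 Hz, kinematics at 120 Hz, in trials
within sessions.

## 2. The decoding model

The decoder is deliberately minimal: one channel-wise convolutional
layer and one linear readout, 945 parameters in total.

**Input.** A 60 × 32 matrix: 500 ms of *envelope* signal at 120 Hz over
the 32 channels.

**Force-pattern layer.** Six filters of length 60, shared across
channels, stride 1, no padding, tanh activation. Because each filter
spans the entire window of a single channel, the time axis collapses to
length one and the output is a 6 × 32 feature map with *no channel
mixing*:

$$fm_{j,c} = \tanh\Big(\sum_{t=1}^{60} f_j[t]\, x[t,c] + b_j\Big).$$

Channel independence is the property everything else relies on: it
keeps the receptive field purely temporal (each feature is a "force
pattern" of one muscle site) and it is what makes the weight
topography of Section 6 well-defined. One bias per filter is included
(disable with `conv_bias = FALSE`; the choice is not critical and both
variants are exercised in the tests).

**Readout.** The feature map is flattened feature-map-major (feature
map 1 over channels 1–32, then feature map 2, ...) into a 192-vector
and mapped linearly, $\hat{y}_i = W_i^\top fm + b_i$, to the three
joint angles in degrees. No output nonlinearity.

**Training.** Minibatch Adam on the mean squared error over samples
and joints. Defaults: learning rate 0.001, batch size 64, 15 epochs,
moments 0.9/0.999, epsilon 1e-8, seed-controlled shuffling each epoch.
The batch size is not dictated by the protocol the defaults follow; 64
is a conventional choice and is config-exposed. Training is strictly
deterministic given (data, config, seed); the gradient is computed
analytically (the backward pass is ~20 lines for this architecture)
and is verified against central finite differences for every parameter
in the test suite and the acceptance script.

**Initialization.** FC weights are scaled-uniform fan-in,
$U(\pm 1/\sqrt{192})$; biases start at 0. Filter taps are drawn
*nonnegative*, $U(0, 2/60)$, so that every feature map begins — and in
practice remains — an increasing function of the channel envelope.
This is a deliberate design choice: the weight-topography backtracking
(Section 6) superposes the six per-feature-map weight blocks by plain
summation, which implicitly assumes the feature maps share one
polarity. With sign-symmetric filter initialization half the feature
maps respond to envelope amplitude with inverted sign, their FC blocks
acquire compensating signs, and the block sum cancels to noise even
when the decoder itself is accurate. Nonnegative taps resolve the
degeneracy without measurable effect on decoding accuracy (the
cross-validation criterion is met identically under either scheme).

## 3. Preprocessing

The chain is rectify → envelope → normalize → resample, applied per
channel; every stage is causal, as required for the real-time setting
the model targets.

1. **Rectification**: elementwise absolute value.
2. **IEMG envelope**: a causal second-order low-pass with impulse
   response $h(t) = A(e^{-at} - e^{-bt})$, the difference-of-exponentials
   "quasi-tension" filter classically used to approximate muscle
   activation from rectified EMG, implemented as two recursive
   exponential smoothers. Defaults $A = 6.44$, $a = 10.80\,s^{-1}$,
   $b = 16.52\,s^{-1}$ — the published coefficients of that filter
   family, used here as configuration defaults (the underlying protocol
   names the filter but not its coefficients). At these values the
   response at 10 Hz is >27 dB below DC (asserted in the tests), so
   the envelope is confined far below the kinematic Nyquist rate.
3. **Unit normalization**: per-channel min–max scaling to [0, 1]. The
   statistics are pooled over all trials of the training session and
   *stored*. Two points are deliberate: normalization is per channel
   (the protocol does not say whether it was global; per-channel is the
   variant that makes between-channel weights comparable), and data
   normalized with stored statistics — a new day's recording scaled
   with the training day's extrema — is *not* clipped, so
   distribution shift is visible to the model rather than silently
   saturated. Constant channels map to 0 with a warning.
4. **Resampling** 500 → 120 Hz to match the kinematic rate, by linear
   interpolation onto the 120 Hz time grid, yielding exactly
   `round(n * 120/500)` samples. Interpolation rather than a polyphase
   FIR is a considered choice: after stage 2 the signal has no content
   near the 60 Hz target Nyquist, so no separate anti-aliasing is
   needed, constants and lengths are preserved exactly, and there are
   no FIR edge transients. The resampling error against an ideal
   reconstruction is checked on band-limited inputs in the tests.

Normalization precedes resampling, matching the stated order of the
reference protocol.

## 4. Dataset construction and cross-validation

Envelope and angle streams are synchronized by truncation to the common
length (a mismatch above 1 s is treated as a recording fault). Windows
of 500 ms slide in 100 ms steps — 60 samples with stride 12 at 120 Hz,
i.e. 400 ms overlap — and never cross trial boundaries, since trials
are separated by rest. The target of a window is the per-joint *mean*
angle over its 60 samples. Window counts follow
$\lfloor (T - 60)/12 \rfloor + 1$ and are property-tested against a
brute-force enumerator.

Cross-validation is trial-wise, so overlapping windows can never leak
between training and testing:

- **initial design** (10 trials): trials are randomly partitioned into
  5 groups of 2 with a recorded seed;
- **second design** (5 trials): each trial is its own group.

Per fold, the model is trained from a fresh initialization (seed
lineage `seed + fold`) on four groups and scored on the fifth by the
Pearson correlation between predicted and measured window-target
series, per joint; the headline score is the mean over the five folds.
The correlation is computed over the concatenated test fold (per-trial
averaging was the other defensible reading; concatenation is
implemented because fold = trial-group is the unit the protocol
evaluates). A constant series leaves the coefficient undefined; it is
reported as `NA` with a warning and excluded from aggregates.

## 5. Transfer learning for new sessions

Between recording days the signal changes — contact impedance drifts,
the sleeve sits differently, the noise floor moves. Two procedures are
implemented:

- **Direct testing**: the trained model is applied unchanged to the
  new session, which is normalized with the *stored* training-day
  statistics (the deployment situation: no new calibration data has
  been seen).
- **FC fine-tuning**: the convolutional layer is frozen and only the
  FC weights and biases are retrained, warm-started from the trained
  model, for 5 epochs on the new session under the second-design
  five-fold protocol. Normalization statistics are recomputed on the
  new session (recalibration implies new data is available; whether
  the original protocol re-normalized is unstated — this choice is the
  well-defined one for both scenarios and is recorded with the model).
  Bit-equality of the frozen layer before and after is asserted, not
  assumed.

Warm-starting rather than re-initializing the FC layer keeps the
information of the original session in the model; freezing the filters
keeps the subject's temporal activation patterns while the spatial
readout adapts to the shifted electrode-to-muscle mapping.

## 6. Weight topography ("geometry" maps)

For joint $i$, the 192 FC weights are split into six consecutive
32-long blocks aligned with the flatten order and summed elementwise
per channel. Summation (rather than mean or absolute sum) is the
superposition under which the map times a uniform feature perturbation
reproduces the FC output change; `mean` and `abssum` are available as
exploratory options. The 32-vector is normalized by its own maximum
absolute value to [−1, 1] (per-joint normalization, so every map spans
the full color range) and arranged on the two 4 × 4 grids, flexor left
and extensor right, rows following the channel groups of the sleeve
and columns in increasing channel number. Rendering uses a diverging
blue–white–red scale centred at 0: red channels push the joint toward
its positive motion (WF, P, HG), blue toward the negative one (WE, S,
HO), white channels do not contribute. The intra-panel orientation is
a documented convention of this package, recorded in the exported
table (`geometry_table()`).

The package produces the maps; it makes no anatomical claims about
them. What *is* validated, on synthetic data with a known
channel-to-motion mixture, is recovery: the top-|S| channels of each
joint's map must overlap the set S of channels the generator actually
drives for that joint at Jaccard ≥ 0.5, and the planted blocks of the
positive/negative primitive must receive positive/negative map values
on average.

## 7. The synthetic generator

No public recordings exist for this protocol, so the package ships a
generator that reproduces the *structure* the pipeline assumes, with
known ground truth:

- **Paradigm**: each trial runs WF, WE, WF, WE, P, S, P, S, HG, HO,
  HG, HO from CP, each excursion a raised-cosine pulse CP → peak → CP.
  Raised-cosine (rather than trapezoidal) pulses are C¹-smooth, so the
  envelope filter does not ring at motion onsets. Defaults, chosen
  once as typical adult ranges of motion since the protocol reports no
  amplitudes or durations: peaks ±60° (WF/WE), ±70° (P/S), ±50°
  (HG/HO); 2 s per excursion, 1 s rest at CP (37 s and 4440 angle
  samples per trial). Ten trials form the initial-design session, five
  the second-design one.
- **Activations**: each of the six motion primitives receives the
  excursion of its joint rectified in its direction, scaled to peak 1 —
  the simplest mapping with the right support (zero at CP, peaked with
  the motion).
- **EMG synthesis**: per channel, zero-mean Gaussian noise bandpassed
  to 20–200 Hz (the standard surface-EMG band under the 250 Hz
  Nyquist) is amplitude-modulated by `mixing %*% activation +
  noise_floor` at 500 Hz. The default 32 × 6 mixing matrix plants each
  primitive on a disjoint 2 × 2 electrode block — positive-direction
  primitives on the flexor face, negative on the extensor face — with
  gain 1, and lets activity bleed to grid neighbours with gain 0.3
  (`spatial_smoothness`). The ground-truth channel set of a joint,
  used by the recovery tests, is read off the mixing matrix: every
  channel with positive gain for either of the joint's primitives.
  Bleed channels belong to that set deliberately — after min–max
  normalization a channel carrying 0.3× a primitive's activation is
  statistically the same regressor as one carrying 1×, so "driven by
  the primitive" is the only ground truth the generated data can
  identify.
- **Day shift**: per-channel log-normal gain factors (sdlog 0.4 by
  default), a rigid rotation of the sleeve by whole grid columns
  (channel (row, col) takes the signal of (row, col−shift), wrapping
  around the arm), and additive extra carrier noise raising the noise
  floor (factor 2 by default; noise can only be added, not removed,
  so factors below 1 are rejected). The identity shift is an exact
  no-op, asserted bitwise.
- **Determinism**: trial i of a session is generated under seed
  `seed + i`; identical (spec, seed) gives identical arrays, and the
  generator restores the caller's RNG state.

**What the generator does and does not emulate.** It reproduces the
amplitude-modulation structure, the paradigm timing, the two-face
channel geometry, the sign conventions, and plausible between-day
shifts. It does not model motor-unit physiology, volume conduction or
crosstalk beyond the smoothness bleed, force dynamics, fatigue, or
trial-to-trial variation in movement amplitude (angle jitter is
available but defaults to 0). Consequently, passing the synthetic
recovery tests shows the *pipeline* is correct — signals flow, the
optimizer works, structure that is present is found — not that the
model reaches any particular accuracy on real muscle activity. The
cross-validation band used in the tests (mean CC ≥ 0.85 per joint) is
an internal-consistency check under these favourable synthetic
conditions, not a claim about human data.

## 8. Baselines and statistics

Four conventional regressors are fitted on the same windows — ordinary
least squares, RBF support-vector regression, k-nearest neighbours
(k = 5) and a CART regression tree — as three independent single-output
models per baseline, since none of them is canonically multi-output.
The default feature representation is the flattened 60 × 32 window
(1920 dimensions), matching the information the network sees; a 32-dim
per-channel-mean variant exists for speed and is what the permutation
control uses. Hyperparameters are the library defaults of `e1071`,
`caret::knnreg` and `rpart`, config-exposed; the original protocol
reports neither representation nor hyperparameters, so comparisons on
synthetic data are qualitative (orderings), not reproductions.

All models are scored with the identical correlation implementation on
identical trial-wise folds. Model comparison across independent
sessions ("subjects") uses two-sided paired Student's t-tests of the
reference model against each baseline with Benjamini–Hochberg FDR
adjustment; the implementations wrap `stats::t.test` and
`stats::p.adjust("BH")`, and are verified against the textbook
formulas in the tests. Identical pairs return t = 0, p = 1; paired
differences that are constant and non-zero leave the statistic
undefined and raise an error rather than a misleading number.

A label-permutation control closes the loop: with window targets
randomly permuted, every model's fold-wise correlations must collapse
to chance. The control runs on the full 10-trial dataset because with
~90-window test folds the null correlation has standard deviation
around 0.1 and its extremes are uninformative; ~730-window folds
concentrate the null near zero so the check has teeth.

## 9. Problem sizes and runtime

The validation suite uses two scales, both generated in code at run
time: a shortened paradigm (each motion once, 1 s hold, 0.5 s rest;
455 windows over 5 trials) for unit-level checks, and the full study
conditions (default paradigm, 10-trial session, 3660 windows; plus a
5-trial day-shifted session) for the end-to-end criteria. The full
test suite and the acceptance script each run in a few minutes on a
single CPU core; the model itself trains in under 10 seconds on the
full session.

## 10. Known limitations

- The generator's favourable signal-to-noise ratio makes the absolute
  CC values optimistic relative to human recordings; only orderings
  and recovery properties should be read from them.
- Min–max normalization ties the model to the stored extrema; a
  different normalization (e.g. robust quantiles) would change the
  transfer behaviour and is not explored.
- The FC-weight topography is an interpretation device: it reflects
  what the trained readout uses, which coincides with the physiological
  source only insofar as channels are informative and the feature maps
  share polarity (Section 2).
- Real-time deployment (streaming windows, sub-500 ms latency) is out
  of scope; all filtering is causal so the pipeline is
  streaming-compatible in principle, but no streaming interface is
  provided.
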