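---
title: "Fault-tolerant sEMG movement classification with virtual sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fault-tolerant sEMG movement classification with virtual sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsentry)
```

## The problem

Myoelectric prostheses classify hand and arm movements from multichannel
surface electromyography (sEMG). In daily use individual electrodes
degrade: they shift on the skin, pick up mains or cardiac interference,
saturate the amplifier, or are swamped by motion artifacts. A classifier
trained on clean signals then loses accuracy, often catastrophically,
even though most channels are still fine.

`emgsentry` implements a fault-tolerant processing chain around a
*virtual sensor*: degraded channels are detected online and their signal
is replaced by a model-based estimate computed from the channels that are
still clean, so the downstream movement classifier keeps operating on a
full electrode set without retraining. Because no public corpus can be
bundled, the package ships a seeded synthetic generator that emulates a
12-electrode, 17-movement, 6-repetition acquisition protocol at 2 kS/s
(5 s movement, 3 s rest), so the whole chain is reproducible end to end.

## Pipeline

1. **Contamination** (`apply_case()`): one of five canonical contaminants
   is added to the raw signal of the channels of one of sixteen
   degradation cases, before any filtering. The simulators are
   motion artifact (low-frequency stochastic drift with a small broadband
   pop component, unit power by default), electrode displacement
   (additive white Gaussian noise at 15 dB SNR), amplifier saturation
   (six sinusoids with random frequencies in 200--240 Hz), power line
   (60 Hz fundamental of 0.4 V plus harmonics at amplitude/k), and ECG
   bleed-through (synthetic P-QRS-T template scaled to peak 0.2).
2. **Preprocessing** (`bandpass_filter()`, `rectify_normalize()`,
   `segment_windows()`): order-20 Butterworth band-pass, 20--500 Hz,
   applied with zero phase; per-channel max-absolute normalization over
   the full record (the offline normalization used when no
   maximum-voluntary-contraction calibration exists); sliding windows of
   300 ms advanced by 75 ms.
3. **Detection** (`train_detector()`, `detect_recording()`): a two-class
   RBF-kernel SVM flags each (channel, window) as clean or contaminated
   from nine window features.
4. **Activation** (`update_activation()`): per channel, the virtual
   sensor engages when more than 70% of the sliding windows in the
   trailing 3 s are flagged, and the channel is marked for classifier
   retraining without it when at least 80% of all windows are flagged.
   The 70%-of-3 s rule implies a burst must last longer than about 2.1 s
   to trigger replacement; this is verified as a property over burst
   placements.
5. **Reconstruction** (`reconstruct_channel()`): the multichannel
   cross-correlation (MCC) matrix turns the remaining clean channels into
   an exogenous input `u(n)` -- the correlation-weighted channel sum --
   and either a time-varying ARMA model (TVARMA) or a steady-state Kalman
   estimator (TVK) maps `u` onto the degraded channel.
6. **Classification and evaluation** (`run_setting()`, `anova3()`):
   an 18-class one-vs-all RBF-SVM with majority voting over the last
   three windows, evaluated over the 20 repetition-wise folds
   (train on 3 of 6 repetitions), across seven settings that contrast no
   intervention, channel removal with retraining, and virtual-sensor
   replacement with and without retraining; a three-factor full-factorial
   ANOVA decomposes mean accuracy into setting, contaminant and channel
   case effects.

## The virtual sensor

For target channel $t$, every other channel $x$ contributes
$p_{x,t} = c_{x,t} / \sum_{x'} c_{x',t}$, where $c_{x,t}$ is the absolute
Pearson correlation computed on a recent clean history; excluded
(contaminated) channels have their row zeroed and the normalization is
redone, so the weights over available sources always sum to one and the
input $u(n) = \sum_x p_{x,t}\, y_x(n)$ is a convex channel combination.

**TVARMA.** The channel is modelled as
$y(n) = \sum_{i=1}^{P} a(i,n)\, y(n-i) + \sum_{j=1}^{Q} b(j,n)\, u(n-j) + e(n)$
with $P = 4$, $Q = 2$, and coefficients expanded on a basis
$a(i,n) = \sum_{m=0}^{V} \alpha(i,m) f(n,m)$ (default: Legendre
polynomials on time normalized to $[-1, 1]$, $V = 2$; cosine and raw
time-power families are selectable). Coefficients are estimated by least
squares on the implied linear regression. Two estimation modes exist:

* `"joint"` regresses on the $y$- and $u$-lag regressors together. This
  is the plain least-squares reading of the model equation and is what
  the package's estimation oracle and parameter-recovery tests exercise.
  It is optimal for one-step prediction -- but on strongly
  autocorrelated signals the $y$-lags absorb nearly all weight, so the
  zero-innovation *free run* a virtual sensor needs (there are no clean
  measurements of the degraded channel to feed back) collapses.
* `"two_stage"` first fits the input map ($u$-lags only) and then the AR
  dynamics of its residual. The mean free-run prediction is then the
  time-varying input map applied to $u$; the residual AR term decays
  from an unknown state and is taken as zero. `reconstruct_channel()`
  uses this mode.

Free-running a least-squares AR part is not guaranteed stable, so the
prediction step projects the instantaneous AR polynomial's roots onto
radius 0.99 before recursing, and clips the output at a guard bound as a
last resort; both events are logged.

**TVK.** A state-space model with identity state matrices: the state
tracks the channel, driven by the MCC input, with process noise
covariance $Q_w$ and measurement noise covariance $R$. The innovation
gain comes from iterating the discrete algebraic Riccati equation to a
fixed point (residual below $10^{-10}$); the scalar golden-ratio closed
form is used as a test oracle. Defaults: $R$ is the residual variance of
the MCC input as a predictor of the clean history and $Q_w = 0.1 R$.
While a channel is degraded its measurement is still fed to the filter,
but with $R$ inflated tenfold so the estimate leans on the MCC input.
One numerical subtlety: with identity $A$ the state equation integrates
its input, which would amplify a band-limited input by the reciprocal
innovation gain at low frequency. The reconstruction therefore feeds the
MCC input *incrementally* (initial state $u(1)$, input $\Delta u$),
which preserves the literal gain recursion and identity matrices while
giving unit DC gain from the input -- the estimate is then the intended
convex blend of the input path and the measurement.

## The synthetic generator: what it emulates, and what not

Channels are driven by shared band-limited (20--450 Hz) Gaussian
carriers with a steeply decaying spectrum (4th-order low-pass tilt at
120 Hz; median frequency near 100 Hz, negligible power above ~300 Hz, as
in real surface recordings). The generator is organised around *muscle
synergies*: each channel loads mainly on one of three synergy groups
(plus a weak global source), and each movement drives the synergies with
its own nonnegative intensity vector, skewed so some groups are nearly
silent per movement. Movement-specific per-channel gains are the synergy
product with $\pm 15\%$ multiplicative jitter; each repetition
additionally re-draws a $\pm 15\%$ per-channel gain factor, emulating
the repetition-to-repetition amplitude variability of real contractions.
Movement onsets use a 250 ms raised-cosine ramp (a step onset would be a
motion-artifact look-alike); rest is independent baseline noise 20 dB
below the mean movement RMS, since real recordings are never silent.

These choices matter for what the tests can and cannot show:

* The synergy structure is what makes the MCC virtual sensor meaningful:
  the channels most correlated with a degraded electrode share its
  synergy, so their weighted sum tracks its movement-wise activation,
  including its silent movements. On uncorrelated channels the method is
  vacuous by construction.
* The repetition jitter is what gives channel removal (setting 3) a real
  cost and the reconstruction-retraining settings their margin; without
  it any sufficient channel subset classifies perfectly and all
  fault-tolerance comparisons collapse into exact ties.
* Everything is additive and linear-Gaussian. Real degradations
  (electrode lift-off, true saturation clipping) are nonlinear, and real
  sEMG is spikier than a Gaussian carrier. In particular, 15 dB additive
  white noise -- the printed displacement simulation -- barely moves
  z-scored window features here, so a clean-trained classifier loses
  almost nothing to it, and the replacement settings cannot "recover"
  accuracy that was never lost. The package reports that comparison
  honestly rather than tuning the fixture until it flips; the
  saturation and motion-artifact recoveries, which are large, reproduce
  clearly.
* Detection difficulty is realistic in ordering: saturation and power
  line are near-perfectly detectable, motion artifact easily, broadband
  displacement noise well but not perfectly, ECG hardly at all from
  300 ms windows (consistent with cardiac interference being the
  weak case for window-level detectors).

## Detector features

The detector uses the five classification features (MAV, RMS, WL, MFL,
PWR) plus four spectral descriptors: spectral centroid, fraction of
power below 20 Hz, fraction in 55--65 Hz, and fraction above 350 Hz.
The first three spectral terms expose drift and mains interference; the
high band is the standard noise-floor cue -- surface EMG carries almost
no power above ~300 Hz, so a flat added noise floor stands out there
even when it is invisible in amplitude features during a strong
contraction. A 3-fold cross-validated grid search selects `(cost,
gamma)`; feature scaling is frozen at training.

## Numerical choices

* The order-20 band-pass is designed as cascaded second-order sections
  (analog Butterworth prototype, low-pass-to-band-pass transform,
  bilinear transform with prewarping). A direct-form order-20 transfer
  function is numerically unusable at a 0.02 normalized edge. Zero-phase
  filtering runs the full cascade forward and backward over an
  odd-reflection-padded signal (about three periods of the lower edge),
  with the gain distributed across sections; per-section zero-phase
  filtering rings at the near-unit-circle low-frequency poles.
  Prewarping places the half-power points exactly at 20 and 500 Hz.
* Window label ties resolve to the lower label id; three-way voting ties
  resolve to the current window's raw prediction. Both rules are
  deterministic and latency-free.
* The activation logic counts windows fully covered by the trailing 3 s
  buffer, with unfilled positions treated as clean; activation therefore
  requires a genuinely sustained degradation. A hysteresis (deactivate
  below 35%) keeps an imperfectly flagged channel from toggling its
  replacement on and off; the source method specifies the activation
  threshold but no deactivation rule.
* Rank-deficient least-squares systems fall back to a small ridge
  penalty and say so; constant windows return a sentinel MFL with a
  warning; an all-zero channel passes normalization unscaled with a
  warning.
* Offline, contamination spans the whole record, so there is no clean
  trailing buffer to calibrate on; `evaluate_fault_tolerance()` fits the
  MCC matrix and the virtual-sensor models on one repetition of each
  movement (`history_mode = "per_movement"`), the offline analogue of
  the online pre-degradation buffer (`"first_seconds"` is available).

## Problem sizes

The shipped tests and examples run a desk-scale study: 12 movements,
6 repetitions, 2 s movement / 1 s rest at 2 kS/s (about 7 minutes of
12-channel signal), detector trained on a separate 2-repetition session,
and 2 of the 20 repetition folds, with the displacement, saturation and
motion-artifact contaminants at a single-channel and a four-channel
degradation case. The full protocol (17 movements, 5 s/3 s, all 20
folds, all 16 cases, all five contaminants) is a parameter change, not a
code path change.

## Known limitations

* Saturation is simulated as additive narrowband tones per the source
  description, not as amplifier clipping; a clipping variant would be
  nonlinear and is out of scope.
* The per-movement amplitude coupling that MCC reconstruction relies on
  is exactly low-rank here; real synergy structure is approximate, so
  real reconstruction error will be larger than the fixture suggests.
* The TVK measurement-feed policy during contamination (inflated $R$)
  is a modelling choice; the alternative of dropping the measurement
  entirely reduces the filter to the input path.
* Multiple comparisons use per-group 95% confidence intervals with a
  disjointness rule, not a named post-hoc procedure.
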