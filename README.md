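# emgsentry

Fault-tolerant surface-EMG movement classification with virtual sensors.

Myoelectric prostheses decode hand and arm movements from multichannel
surface electromyography (sEMG). In daily use individual electrodes
degrade — they shift on the skin, saturate the amplifier, or pick up
mains, cardiac or motion interference — and a classifier trained on
clean signals loses accuracy even though most channels are still fine.
`emgsentry` implements, end to end and fully reproducibly, a
fault-tolerant processing chain for this problem: it simulates the five
canonical sEMG contaminants over sixteen channel-degradation cases,
detects degraded channels online with a two-class SVM plus temporal
activation logic, replaces them with a *virtual sensor*, and quantifies
accuracy recovery across seven classification settings with a
three-factor ANOVA. It is aimed at researchers in myoelectric control
and biomedical signal processing who want a transparent, testable
reference implementation.

## The method in brief

**Multichannel cross-correlation (MCC).** For a degraded target channel
*t*, every clean channel *x* contributes with weight

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>x,t</sub> = c<sub>x,t</sub> / Σ<sub>x′</sub> c<sub>x′,t</sub>,

where c<sub>x,t</sub> is the absolute Pearson correlation on a recent
clean history (contaminated channels' rows are zeroed and the weights
renormalized). The exogenous model input is the convex channel sum
u(n) = Σ<sub>x</sub> p<sub>x,t</sub> y<sub>x</sub>(n).

**TVARMA virtual sensor.** The channel is modelled as

&nbsp;&nbsp;&nbsp;&nbsp;y(n) = Σ<sub>i=1..P</sub> a(i,n) y(n−i) + Σ<sub>j=1..Q</sub> b(j,n) u(n−j) + e(n),

with P = 4, Q = 2 and time-varying coefficients expanded on a finite
basis, a(i,n) = Σ<sub>m=0..V</sub> α(i,m) f(n,m) (Legendre polynomials
by default, V = 2), estimated by least squares.

**TVK virtual sensor.** A state-space estimator with identity state
matrices whose innovation gain M = P Cᵀ(C P Cᵀ + R)⁻¹ comes from the
fixed point of the discrete algebraic Riccati equation; during
contamination the measurement covariance R is inflated so the estimate
leans on the MCC input.

**Detection and activation.** A two-class RBF-SVM flags each 300 ms
window (75 ms increment) of each channel; the virtual sensor activates
when more than 70% of the windows in the trailing 3 s are flagged
(which implies noise bursts under ~2.1 s never trigger it), and a
channel is removed for classifier retraining at 80%.

**Evaluation.** 18-class one-vs-all RBF-SVM with majority voting over
the last three windows, 20 repetition-wise folds, seven settings
(clean; contaminated; retrain without the channel; TVARMA/TVK
replacement with and without retraining), and a full-factorial
three-way ANOVA of mean accuracy.

Because the reference corpus cannot be bundled, the package includes a
seeded synthetic generator emulating the 12-electrode, 17-movement,
6-repetition protocol at 2 kS/s, with muscle-synergy correlation
structure so the MCC reconstruction is meaningful. See the methods
vignette (`vignettes/fault-tolerant-semg.Rmd`) for the model,
assumptions and design choices.

## Worked example

```r
library(emgsentry)

protocol <- emg_protocol(seed = 0, n_movements = 4, n_repetitions = 6,
                         movement_duration = 2, rest_duration = 1)
protocol
#> <emg_protocol> 4 movements x 6 repetitions, 2 s move / 1 s rest,
#>   12 channels at 2000 S/s (total 72 s), seed 0

rec <- synth_recording(protocol, seed = 7)

# contamination detector, trained on a separate calibration session
calib <- synth_recording(emg_protocol(seed = 1, n_movements = 4,
                                      n_repetitions = 2,
                                      movement_duration = 2,
                                      rest_duration = 1), seed = 21)
detector <- train_detector_from_recording(calib, seed = 5,
                                          n_per_class = 400)
detector
#> <sftd_model> RBF-SVM contamination detector (cost 100, gamma 0.05)
#>   trained on 600 windows; held-out accuracy 88.0%

# saturate channel 2, then compare: clean classification (setting 1),
# classification of the contaminated signal (setting 2), and the
# TVARMA virtual-sensor replacement (setting 4)
results <- evaluate_fault_tolerance(
  rec, detector, kinds = "saturation", cases = 2L, settings = c(1, 2, 4),
  folds = enumerate_kfolds(6, 3)[c(1, 10), ], cost_grid = 10)
summarize_accuracy(results)
#> # A tibble: 3 × 6
#>   setting contaminant  case mean_accuracy sd_accuracy n_folds
#>     <dbl> <chr>       <int>         <dbl>       <dbl>   <int>
#> 1       1 saturation      2          95.7       0.135       2
#> 2       2 saturation      2          36.1       9.93        2
#> 3       4 saturation      2          94.6       0.607       2
```

Saturating a single electrode collapses the 5-class (4 movements +
rest) accuracy from 95.7% to 36.1%; replacing the degraded channel with
the TVARMA virtual sensor — without retraining the classifier —
restores it to 94.6%. `autoplot()` methods exist for recordings,
MCC matrices, evaluation tables and fitted ANOVA models, and
`tidy()`/`glance()` for the fitted model objects.

A thin command-line front end over the same functions is installed at
`inst/cli/emgsentry.R` (subcommands `simulate`, `contaminate`,
`preprocess`, `features`).

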