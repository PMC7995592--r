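---
title: "Methods: estimating functional balance from TUG accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating functional balance from TUG accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Falls in older adults are strongly associated with poor balance, but the
clinical instruments that quantify balance — here the Short Form Berg
Balance Scale (SFBBS), seven items each scored 0/2/4 for a total of 0–28 —
require a trained rater. `tugbalance` implements a surrogate: a single
waist-mounted tri-axial accelerometer worn during a 3-m Timed Up and Go
(TUG) test, from which the SFBBS total is estimated by penalized
regression, and per-item high/low balance risk by penalized logistic
regression.

The modelling chain is:

1. **Calibration.** The raw axes (V downward-positive, ML right-positive,
   AP anterior-positive, units of g, nominally 45 Hz) are rotated into a
   horizontal–vertical frame using the gravity vector measured over a
   still sitting window. We estimate tilt from the mean acceleration over
   that window and apply the rigid pitch-then-roll rotation mapping it
   onto V. The rotation preserves per-sample norms and is idempotent. A
   staticness guard (per-axis SD < 0.05 g) rejects windows containing
   movement.
2. **Segmentation.** The AP axis traces an "M" during a TUG: a hill at
   sit-to-stand (SiSt), a valley while walking, a second hill at
   stand-to-sit (StSi). Landmarks: p1 = departure from steady state,
   p2/p3 = the two M maxima, p4 = return to steady state. Phases are the
   half-open intervals [p1,p2), [p2,p3), [p3,p4), so the three phase
   durations sum exactly to the TUG duration.
3. **Features.** 67 features: TUG duration; per-axis amplitude statistics
   (max/min/range/RMS) and two-part jerk slopes for each transition;
   walking RMS, step length, cadence, gait speed, step/stride times and
   their CVs, dominant FFT frequency, first-quartile spectral mass, and
   the ratio of even to odd harmonics (REOH) per axis; the SD of the two
   transition durations; age and gender.
4. **Estimation.** Elastic-net regression of the SFBBS total, evaluated
   under a 100-iteration random-shuffle-split protocol (80/20, inner
   10-fold tuning of the mixing weight and penalty); MAE and RMSE on each
   held-out split; selection frequency and accumulated-|coefficient|
   importance aggregated across iterations. Item-level risk (scores 0/2 =
   high, 4 = low) uses the same protocol with a binomial link, reporting
   confusion-matrix metrics and ROC/AUC.

## Segmentation: operationalizing "steady state"

The landmark definitions come from the M-shape morphology; two details are
deliberately ours:

* The steady-state band is `baseline mean ± 3 SD`, with the baseline taken
  from the first second of the recording. Because peak detection runs on a
  0.25-s moving average whose samples are serially correlated, the band SD
  is estimated from the *raw* AP baseline and scaled by `1/sqrt(w)` (w =
  smoothing window in samples) — the empirical SD of the smoothed baseline
  underestimates the band and made nearly half the rest samples fall
  outside it.
* Steady state is a dwell notion: only out-of-band runs of at least 0.5 s
  interrupt it. p1 is the last in-band sample before the first sustained
  departure preceding p2; p4 is the first in-band sample after the last
  sustained departure following p3. The literal "last in-band sample
  before p2" rule latches onto the zero-crossing between the anticipatory
  trunk-lean dip and the rise of the SiSt hill and is avoided on purpose.

The two M maxima are the two most prominent local maxima separated by at
least 3 s (below any plausible 6-m walk time); height ties break toward
earlier time. Whether the maxima are read off the smoothed or the raw
series is unstated in the source morphology; we use the smoothed series,
consistently with the peak detector.

On the simulator at noise SD 0.02 g, 100-seed landmark recovery achieves a
median absolute error of about 0.02 s and a maximum near 0.13 s (the
acceptance suite asserts median < 0.1 s, max < 0.3 s).

## Feature choices that needed a decision

* **Units.** All accelerations in g; jerk slopes in g/s (least-squares
  slope of acceleration over each transition part).
* **Transition split.** Each transition divides into a preparatory part
  and an active part at the interior extremum of opposite sign to the hill
  apex (fallback: midpoint). The split is computed per axis on the raw
  signal of the axis being featured.
* **Δjerk sign** is part 2 minus part 1.
* **"First quartile of FFT"** is the percentage of total spectral
  magnitude (DC excluded) at frequencies at or below Nyquist/4. The
  source gives no formula; the interpretation is isolated in
  `fft_first_quartile()`.
* **REOH** uses harmonics 1–20 of the stride frequency (10 even, 10 odd),
  each magnitude read at the nearest FFT bin, stride frequency taken as
  1 / mean stride time; harmonics at or above Nyquist are dropped and the
  denominator is guarded by machine epsilon.
* **Step vs stride.** A step event is one vertical-axis peak; stride times
  are lag-2 differences of step events. Step/stride CVs use the sample SD
  and require at least four events; feature 65 is the *population* SD of
  the two transition durations, i.e. `|SiSt − StSi|/2` (a two-point sample
  SD would be √2 larger).
* **Gravity.** The V axis is mean-subtracted within the walking segment
  before RMS, FFT and step detection (`subtract_gravity`, default on);
  transition amplitudes keep the gravity offset, since rising and sitting
  tip the trunk through it.
* **Path length** is fixed at 6 m (3 m out + 3 m back), configurable.
* **Step length** is path length divided by the number of steps — the
  only dimensionally sensible reading of "average step length".
* **Missing features** (e.g. CVs with too few steps) are `NA`, never
  silently zero, and are mean-imputed inside training splits only.
* **Indexing.** Sample indices are 1-based (R convention) with half-open
  phase intervals; durations are `(end − start)/rate`, so no off-by-one
  ambiguity survives the choice of base.

## The estimation protocol

The elastic-net objective is the Lagrangian form of the mixed-norm
constraint: squared loss plus
`lambda * ((1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1)`.
Features are standardized inside the fitting routine (penalty fairness
across units of g, s, %, years — gender included); coefficients return on
the original scale. The solver is glmnet; correctness is pinned by oracle
tests against the closed-form ridge solution, OLS on orthonormal designs,
and a direct penalized-likelihood optimizer for the binomial link.

Each protocol iteration draws a random 20% test split, tunes
`alpha ∈ {0, 0.1, …, 1}` and a 50-point lambda grid (from the lasso
`lambda_max` down four decades, shared across alphas) by inner 10-fold CV
minimizing MAE (deviance for the binomial case), refits on the full
training split, and records test metrics and coefficients. Ties in the
inner criterion resolve toward the larger lambda (more parsimonious).
Iteration seeds are `seed + iteration`, so runs are reproducible
end-to-end. Imputation statistics come from the outer training split
(never the test split); standardization happens inside each inner-fold
fit. The inner tuning loop uses a relaxed coordinate-descent threshold
(`cv_thresh = 1e-5`): model selection is insensitive to solver precision
at that level and the protocol runs several times faster; final refits use
glmnet's default.

Feature importance is the accumulated magnitude of standardized
coefficients across iterations, rescaled so the top feature reads 100.
Signed sums could cancel for a feature whose sign flips across splits,
which would contradict their use as importance; magnitudes avoid that.
Selection frequency counts iterations with a nonzero coefficient.

The regression tree (an interpretable baseline) splits greedily by
maximal sum-of-squares reduction `SS_A − (SS_AL + SS_AR)` — equivalently
the between-groups sum of squares — with thresholds at midpoints of sorted
distinct values and ties broken toward lower feature index then lower
threshold. rpart is deliberately not used: the split criterion is part of
the method under study, and the implementation is verified against
exhaustive enumeration.

For item-level classification the "elastic net regression" on binary
targets is read as a binomial (logistic) elastic net — the standard
interpretation; a linear-probability fallback is available behind
`link = "linear"` for sensitivity analysis. High-risk is the positive
class; decisions use threshold 0.5; ROC/AUC is threshold-free, computed by
a threshold sweep whose trapezoid area equals the Mann–Whitney
concordance with ties counted ½. Whether published per-task tables pool
predictions over iterations or average per-iteration metrics is ambiguous,
so both are emitted and labelled (`metrics_pooled`, `metrics_mean`).

## What the simulator emulates — and what it does not

`simulate_recording()` reproduces the statistical structure the pipeline
assumes: an M-shaped AP profile whose first hill rises over SiSt to the
apex at p2 (with an anticipatory opposite-sign dip, so the two jerk parts
differ), a second hill with apex at p3 decaying over StSi, step-frequency
oscillation on V (one peak per step, per-step timing jitter),
stride-frequency sway on ML, a 1-g gravity offset, optional sensor tilt,
and white Gaussian noise. Defaults: 45 Hz, 2 s rest, SiSt 1.5 s, StSi
1.8 s, 6 m at 1.0 m/s, cadence 105 steps/min, hill amplitudes 0.35/0.30 g,
oscillation amplitudes 0.25/0.10/0.06 g, jitter SD 15 ms, noise SD
0.02 g — magnitudes a trunk accelerometer typically sees in older adults
walking at comfortable pace.

`simulate_cohort()` draws a latent balance ability b ~ N(0,1) that
monotonically drives gait speed, cadence, step-time jitter and transition
durations, and generates SFBBS items by ordinal thresholding of b plus
item noise onto {0,2,4}, with graded difficulties (eyes-closed standing
easy, single-leg stance hard; roughly a third of an average cohort scores
0 on the hardest item). Demographics mimic a community-dwelling elderly
cohort (age ≈ N(72, 7) truncated at 65, ~79% women). The turn at the 3-m
mark is not modelled as a distinct phase — the segmentation collapses it
into walking by design.

The simulator is *not* a biomechanical gait model: it contains no
double-support dynamics, no turning transient, no sensor drift, no
heteroscedastic noise, and its feature–balance linkage is linear by
construction. A green test therefore establishes that the pipeline
recovers the structure it assumes from signals that contain it — not that
the features are physiologically valid in real cohorts. The headline
numbers published for the 85-participant study this design emulates (mean
MAE ≈ 2, AUCs ≈ 0.72–0.79) require that private dataset and are
reproduced here only as plausibility context, never asserted by the test
suite.

## Numerical choices and degenerate inputs

* Peak prominence is topographic (height above the higher key saddle);
  plateau peaks take their first sample; step peaks need prominence above
  a fraction (default 0.25) of the segment's peak-to-peak amplitude and a
  0.3-s refractory interval.
* FFT features mean-subtract before transforming; flat segments raise a
  numeric error rather than returning 0.
* Metrics with zero denominators (e.g. precision with no predicted
  positives) are `NA`, never 0.
* Protocol iterations whose training split lacks a class (or where an
  inner fold degenerates) are skipped and flagged; at least 90% of
  iterations must remain for a subtask report.
* An unpenalized fit on a rank-deficient design raises a numeric error.
* All randomness flows from a single integer seed per entry point.

## Limitations

* Landmark accuracy is bounded by the 0.25-s smoothing window and the
  dwell rule; pathological recordings without a still start or without a
  return to rest are rejected rather than guessed.
* With fewer than four detected steps the variability features are
  missing and imputed; short or slow walks therefore carry less
  information than the registry suggests.
* The ≥90%-top-5 parameter-recovery guarantee is a property of the
  simulated world (three planted features, linear link); correlated real
  features can spread importance across proxies.
* The package targets 45-Hz waist-worn data; other placements or rates
  will need re-tuned smoothing, prominence and REOH settings.
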