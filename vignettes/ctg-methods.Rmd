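---
title: "Methods: baseline estimation, event detection and risk scoring for intrapartum CTG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline estimation, event detection and risk scoring for intrapartum CTG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctgtools)
```

# The problem

Intrapartum cardiotocography records the fetal heart rate (FHR, beats per
minute) and uterine activity (UC, mm Hg) at 4 Hz during labor. The clinical
question is whether the fetus is developing acidosis (umbilical arterial pH
below 7.05 at birth). `ctgtools` implements a fully interpretable pipeline:
signal cleaning, estimation of the FHR *baseline* (the slowly varying level
the heart rate returns to between events), detection of accelerations,
decelerations and contractions, extraction of 25 named morphological and
variability features from the latest clean 30-minute segment, and a
class-balanced logistic model whose per-feature contributions are reported
next to the predicted risk.

# Preprocessing

Raw exports encode dropout as exact 0 or −1 samples. Maximal missing runs
shorter than 10 minutes with observed anchors on both sides are filled by
linear interpolation (`interpolate_gaps()`); longer runs, and runs touching
a record boundary, stay missing. A cubic Hermite alternative is provided;
its endpoint slopes are taken from the nearest observed neighbour outside
each anchor (Catmull–Rom style), falling back to the across-gap secant at
observation boundaries. Note that any Hermite fill whose two anchor slopes
are estimated independently differs from the linear fill even on one-sample
gaps (the midpoint offset is $(m_0-m_1)h/8$), so the two methods are
compared on accuracy, not sample-for-sample identity; on smooth signals the
Hermite fill is the more accurate of the two, and on affine signals they
coincide.

`select_segment()` then takes the *latest* window of 30 minutes in which
neither FHR nor UC has a missing sample. Windows may start at any sample
(4 Hz granularity). A case is discarded — a value, not an error — when no
such window exists or when the best window starts more than 90 minutes
before delivery (segment start relative to delivery is
`end_offset + (record end − segment start)`; an unknown `end_offset` is
treated as 0). Cleanliness is required of both channels because the
contraction features need gap-free UC; this is an interpretation the
package makes explicit.

# Baseline estimation

The baseline is conceptually the mean FHR with accelerations and
decelerations excluded — a circular definition, since events are themselves
defined against the baseline. The package breaks the circle with a
*stability-weighted median filter*:

1. The signal is band-pass filtered into four modulation bands — 0–0.1,
   0.1–1, 1–3 and 3–7 cycles/min — spanning event time scales from ~9 s to
   beyond 10 min. Band edges are read as cycles per minute of signal
   modulation and converted as $f_{Hz} = f_{cpm}/60$.
2. Eight per-sample stability variables are formed: the absolute first
   difference of each band signal (event slopes have high derivatives) and
   the absolute analytic-signal envelope of each derivative (high across an
   entire event, including its trough, which the derivative alone cannot
   distinguish from baseline).
3. A logistic model on these variables, calibrated on recordings with
   annotated events (`fit_stability_model()`; samples inside annotated
   events are the non-stable class), yields the per-sample probability of
   stability $p_{stab}(t)$.
4. The baseline at $t$ is the lower weighted median of the FHR over the
   window $|t-t'| < T$ with weights
   $W_t(t') = p_{stab}(t')\,\max(0, 1-|t-t'|/T)$: likely event samples are
   excluded, nearby samples count more.

Two modes set the half-duration: **fixed**, $T = T_0 = 20$ min; and
**variable**, $T = T_0/(3\,\bar p_{stab}(t))$ with $\bar p_{stab}(t)$ the
mean stability over $[t-T_0, t+T_0]$ — an unstable stretch widens the
window, a stable one shrinks it so genuine baseline shifts are tracked
faster. The factor 3 keeps the average half-duration near $T_0$; at
$\bar p_{stab} \equiv 1/3$ the two modes coincide exactly, which the tests
exploit as an algebraic identity.

Numerical choices:

* **Filter realisation.** The 6th-order Butterworth design is implemented
  as an analytic biquad cascade (prototype poles + pre-warped bilinear
  transform) applied forward–backward. A single transfer-function
  realisation is numerically unusable at normalized cutoffs of order
  $10^{-4}$ (output diverges past $10^{14}$); the cascade is stable, and
  zero-phase filtering avoids phase lag that would shift event locations.
  Band-passes are realised as HP(low edge) ∘ LP(high edge), the 0–0.1
  cycles/min band as a pure low-pass (0 is not a valid analog band edge).
  Each pass subtracts the leading sample and restores its steady-state
  response, so constants filter exactly and edge transients reduce to
  curvature effects; odd-reflection padding covers three filter time
  constants.
* **Weighted median convention.** The lower weighted median: the smallest
  value whose cumulative weight reaches half the total. The midpoint
  convention would differ only on exact half-mass ties.
* **Variable-mode clamp.** $T$ is clamped to [5, 60] min since the formula
  diverges as $\bar p_{stab} \to 0$.
* **Evaluation grid.** The median is evaluated every 4 samples (1 s at
  4 Hz) and linearly interpolated back; `grid_stride = 1` reproduces the
  exact per-sample definition, and the stride is a pure tractability
  device whose error is far below the estimation error.
* **Degenerate windows.** A window with zero total weight falls back to
  its unweighted median.
* **Stability-model regularisation.** Variables are standardised and the
  logistic fit carries a light L2 penalty (default $10^{-3}$) so separable
  annotations cannot overflow; the fit itself is a deterministic
  Newton/IRLS solver converged to machine precision.

# Event detection

Candidate accelerations are maximal runs with FHR strictly above the
baseline; a run qualifies when its maximum deviation exceeds 15 bpm, its
mean deviation exceeds 10 bpm, and it lasts at least 15 s. The 15-s floor
follows the clinical guidelines' definition of these events; it is
configurable (`min_duration_s = 0` disables it) because the
three-condition amplitude rule can be used alone. Decelerations are the
mirror image; those lasting more than two minutes are flagged *late* (a
duration-based label here, not the contraction-lagged clinical sense).
Samples exactly equal to the baseline break runs — "always above" is read
literally. Areas are deviations integrated over time (bpm·s), making them
sampling-rate invariant. Contractions are runs of UC above 10 mm Hg
lasting more than 30 s, with area measured above the threshold.

# Features

`compute_features()` assembles the 25-feature vector (see
`ctg_feature_names()`): baseline min/median/max; acceleration count, total
duration, area, max depth; deceleration and late-deceleration counts,
durations, areas, max depth; contraction count, duration, area; the joint
deceleration–contraction measures (duration and area of decelerations
outside the union of contraction intervals, and the summed distance from
each deceleration peak to the nearest contraction peak); and the two
variability indices. STV is the mean absolute difference of successive
3.75-s epoch means; LTV is the mean per-minute FHR amplitude (max − min).
Partial trailing epochs/minutes are dropped — a 30-minute segment at 4 Hz
divides evenly into 480 epochs and 30 minutes. Empty event lists yield
zeros, including the peak-time features when a segment has no
contractions.

# Risk model and interpretability

`fit_acidosis_model()` fits a logistic regression of the binary outcome on
a feature subset (default `b_min`, `b_max`, `acc_area`, `dec_area` — the
subset that generalises best across centers). Cases are weighted
$N/(2 N_{class})$ so both classes carry equal total weight; features are
standardised with training-data center/scale stored in the model, which
both stabilises the optimisation and makes the contributions comparable
across features. The solver is the same penalised Newton/IRLS used for the
stability model: it is deterministic, exact in the weights (duplicating a
case while halving its weight reproduces the fit to machine precision),
and the weak default ridge ($10^{-4}$) guards against separation on small
cohorts. `stats::glm` reproduces its solutions as the penalty vanishes and
serves as the independent cross-check in the tests.

The predicted risk is $p = \mathrm{logistic}(\beta_0 + \sum_i \beta_i
x_i)$ and the contribution of feature $i$ is
$c_i = \beta_i x_i / \sum_j \beta_j x_j$, which sums to 1 whenever the
denominator is nonzero; the `positive_only` variant keeps only terms with
$\beta_i x_i > 0$ and renormalises, giving nonnegative contributions that
sum to 1. Evaluation uses the rank-based AUC (ties count one half),
stratified seeded 5-fold cross-validation, and leave-one-center-out
evaluation that refits on all other centers — the protocol that estimates
performance in a previously unseen site.

# The synthetic cohort generator

`simulate_record()` builds FHR as a smooth drifting baseline (sum of two
slow sinusoids inside [110, 160] bpm, drift scale 8 bpm), Hann-shaped
accelerations/decelerations placed by a thinned Poisson process with
overlap rejection, and band-limited Gaussian variability synthesised per
modulation band plus a fast 0.05–0.5 Hz component (targeting STV ≈ 2 bpm
and LTV in the 15–20 bpm range). UC is a ~5 mm Hg resting tone plus
Gaussian-bell contractions every 2–5 minutes (peaks 30–80 mm Hg);
decelerations are time-locked to a contraction peak with probability 0.5
and a 20-s lag. Dropout is inserted as 0-valued runs after ground truth is
recorded. Event rates default to 10 accelerations and 12 decelerations per
hour — ordinary active-labor magnitudes. Event amplitude floors sit at
22 bpm (accelerations) and 25 bpm (decelerations): a Hann bump's mean
deviation is half its peak, so a peak below 20 bpm can never satisfy the
mean-deviation criterion and would not be an event at all.

Outcomes are drawn through a known logistic link on the true (ground
truth) values of the four default features, standardised across the
cohort, with the intercept tuned by bisection to a 10% prevalence.
`simulate_annotated_set()` produces gap-free traces with per-sample
stability labels — exactly the complement of the injected event supports —
for calibrating the stability model and measuring baseline error against a
known truth.

What the generator does **not** emulate: maternal-heart-rate capture and
other sensor artifacts beyond 0-valued dropout, genuine hypoxia
physiology (event shapes are symmetric Hann bumps; real decelerations are
asymmetric and pattern-typed), autocorrelated outcome risk within a
center, or annotation noise. Passing tests therefore demonstrate the
correctness and internal consistency of the algorithms under known ground
truth, not clinical performance; the headline clinical numbers require the
external recordings and cannot be recomputed here.

# Validation design and problem sizes

The test suite and `scripts/acceptance.R` work at sizes chosen to finish
comfortably on one CPU while keeping sampling error far below the margins
being tested: 66 annotated recordings of 30 min (40 calibration / 26
held-out) for the baseline study; 200 30-min segments for detector
sensitivity/FDR; 5000 cases for model recovery with a 10 000-case
Monte-Carlo estimate of the generator's Bayes AUC; 1000 random instances
for the weighted-median and contribution checks. On the held-out
annotated records the three baseline settings reproduce the expected
ordering — calibrated stability weights beat the plain distance-weighted
median, and the variable half-duration beats the fixed one.

A known limitation, deliberately left visible: with realistic drift the
cohort-level minimum and maximum baseline correlate at $r \approx 0.95$,
so the individual coefficients of `b_min` and `b_max` are
poorly identified at $n = 5000$ — the Fisher-information standard error
(~0.17 standardised) exceeds a 15% relative-error band on coefficients of
magnitude 0.8. The recovery check in the acceptance tests keeps the tight
per-coefficient bound and is expected to fail for some cohort draws; the
discrimination check (cross-validated AUC within 0.04 of the Bayes AUC)
is the stable statement of model correctness and passes with an order of
magnitude to spare. No estimator can beat this bound — the weighted and
unweighted maximum-likelihood fits err identically on average — so the
limitation is informational, not a solver defect.

# Reproducibility

Every stochastic step takes an explicit seed: cohort and record generation
derive per-case streams from the base seed, fold assignment is a seeded
stratified shuffle, and repeated runs are byte-identical. Models serialise
to versioned JSON text with 17 significant digits, so coefficients
round-trip bit-exactly.
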