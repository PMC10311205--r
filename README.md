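# ctgtools

Analysis of intrapartum cardiotocography (CTG) for fetal-acidosis risk
scoring, aimed at researchers in perinatal signal analysis. A CTG record
pairs the fetal heart rate (FHR, bpm) with uterine activity (UC, mm Hg) at
4 Hz; the package turns such a record into an interpretable risk of fetal
acidosis (umbilical arterial pH < 7.05 at birth):

1. **Preprocessing** — dropouts (raw 0/−1 samples) shorter than 10 min are
   linearly interpolated; the latest 30-min segment with no missing sample
   in either channel is selected, and cases whose best segment starts more
   than 90 min before delivery are discarded.
2. **Baseline** — the FHR baseline at time *t* is a lower weighted median
   over the window |t − t′| < T with weights

   W<sub>t</sub>(t′) = p<sub>stab</sub>(t′) · max(0, 1 − |t − t′|/T),

   where p<sub>stab</sub> is a per-sample probability of signal stability
   from a logistic model on eight band-filtered derivative/envelope
   variables (bands 0–0.1, 0.1–1, 1–3, 3–7 cycles/min, 6th-order
   zero-phase Butterworth). T is either fixed (20 min) or modulated as
   T = 20 min / (3 p̄<sub>stab</sub>(t)).
3. **Events** — accelerations are maximal runs above the baseline with max
   deviation > 15 bpm, mean deviation > 10 bpm and duration ≥ 15 s;
   decelerations are the mirror image, flagged *late* beyond 2 min;
   contractions are UC runs above 10 mm Hg for more than 30 s.
4. **Features** — 25 named features per segment: baseline min/median/max,
   event counts/durations/areas/depths, joint deceleration–contraction
   measures, and short/long-term variability (STV, LTV).
5. **Model** — class-balanced logistic regression (default features
   `b_min`, `b_max`, `acc_area`, `dec_area`), risk
   p = logistic(β₀ + Σᵢ βᵢxᵢ), with per-feature contributions
   cᵢ = βᵢxᵢ / Σⱼ βⱼxⱼ reported alongside the risk.

A ground-truth simulator (`simulate_record()`, `simulate_cohort()`,
`simulate_annotated_set()`) generates realistic cohorts with known
baselines, event intervals, stability labels and outcome links, so every
stage is testable without clinical data.

## Worked example

```r
library(ctgtools)

# a 5000-case synthetic cohort with a known outcome link
coh <- simulate_cohort(sim_params(n_cases = 5000, seed = 12))
model <- fit_acidosis_model(coh$dataset)
print(model)
#> <ctg_model> logistic acidosis model (pH < 7.05), 4 features
#>   beta0 = -0.5665
#>   b_min                        -0.4316
#>   b_max                        +0.4521
#>   acc_area                     +0.4659
#>   dec_area                     +1.2536

cv <- kfold_eval(coh$dataset, seed = 5)
round(cv$pooled_auc, 3)
#> [1] 0.799

p <- predict(model, coh$dataset[3, ], variant = "positive_only")[[1]]
print(p)
#> <ctg_prediction> risk = 0.482 (positive_only contributions)
#>   b_min                        +0.000
#>   b_max                        +0.407
#>   acc_area                     +0.255
#>   dec_area                     +0.338
```

The coefficient signs match the generator's true link (−0.8, +0.8, +0.5,
+1.2 on the standardised features): a lower minimum baseline, a higher
maximum baseline, and larger acceleration/deceleration areas all raise
the predicted risk (the `b_min`/`b_max` magnitudes are shrunk by their
strong mutual correlation in this draw; see the methods vignette). The
pooled cross-validated AUC (0.799) sits next to the generator's Bayes
AUC (≈0.80) — the model extracts essentially all the discrimination the
simulated features carry. For each case, the positive-only contributions
are nonnegative and sum to one, attributing the risk to individual
features.

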