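# handloc

Analysis of proprioceptive localization errors of hand landmarks measured
with the hand Localization Task (LT).

In the LT, blindfolded-to-the-hand participants point to the perceived
positions of ten occluded hand landmarks (five fingertips and five
knuckles). The relative distances between trial-averaged judgments yield the
*perceived* hand structure, which is classically distorted: finger lengths
are underestimated and the hand width overestimated. `handloc` implements
the error-pattern analysis behind that distortion:

- **Error-vector geometry.** Each trial's systematic error is the vector
  `v = perceived − actual` in a hand-aligned frame, decomposed into a
  medio-lateral component `vx` (negative = lateral, toward the shoulder
  line) and a proximo-distal component `vy` (negative = proximal, toward
  the body), with direction `α = atan2(vy, vx)`.
- **Angle consistency (ITPC).** Each error direction is a unit complex
  vector `e^{iα}`; the inter-trial phase clustering index is the modulus of
  their mean, `|Σ e^{iα}| / n ∈ [0, 1]`, computed within subjects, per
  subject × landmark, and between subjects per landmark × trial cluster,
  with the most frequent direction `θ = arg(mean vector)`.
- **Spatial preprocessing.** Pixel→cm conversion, re-centring, rotation of
  the index–little knuckle line onto the horizontal axis (a rigid isometry),
  and outlier exclusion by squared Mahalanobis distance against the
  χ²(2 df) 95th percentile.
- **Structure metrics.** Estimation ratios (ER = perceived/actual; hand
  width from the index–little knuckle distance, finger lengths from
  tip–knuckle distances), PCA of the subjects × landmarks matrix of mean
  error components, and recomputation of the width ER after removing the
  first principal component (the shared "overlap" bias toward the
  shoulder).
- **Inference.** Linear mixed models (finger × type × normalized trial,
  by-subject random effects) on the error components; Gamma log-link GLMs
  (Wald χ²) on consistency; knuckle trend fits; Bonferroni post-hocs —
  via lme4/lmerTest, car and emmeans.
- **Synthetic-data engine.** Generates LT datasets with per-landmark mean
  error magnitude/direction, target angle consistency (von Mises sampling
  with the concentration solved from I₁(κ)/I₀(κ) = r), subject-, landmark-
  and trial-level noise, and a proximal drift over trials; plus preset
  scenarios spanning the documented error regimes.

## Worked example

```r
library(handloc)
library(dplyr)

ps <- preset_scenarios(n_subjects = 20, n_trials_per_landmark = 16,
                       seed = 42)$sim1_baseline
ds <- generate_dataset(ps)
ds <- mahalanobis_filter(align_dataset(ds))
errors <- error_table(ds)

errors |> group_by(type) |>
  summarise(vx = mean(vx_cm), vy = mean(vy_cm), magnitude = mean(magnitude_cm))
#>   type          vx     vy magnitude
#> 1 fingertip -1.32  -3.24       3.61
#> 2 knuckle   -0.423 -0.676      1.24
```

Fingertip errors are large, proximal and lateral (mean 3.6 cm, pointing into
the third quadrant); knuckle errors are several times smaller — the pattern
that makes fingers look short. Their direction is also more consistent for
fingertips:

```r
cw <- within_subject_consistency(errors)
summarise_consistency(filter(cw, scope == "within_subject_landmark"), type)
#>   type      median_itpc iqr_itpc     n
#> 1 fingertip       0.984   0.0110   100
#> 2 knuckle         0.914   0.0561   100
```

The perceived structure and its model-based decomposition:

```r
er <- estimation_ratios(errors, ds$landmarks)
summarise(er, mean_width_er = mean(width_er),
              mean_length_er = mean(mean_length_er))
#>   mean_width_er mean_length_er
#> 1          1.21          0.683
```

Width ER 1.21 means the hand is perceived 21% too wide (driven by the
index→little lateral error gradient of the knuckles); length ER 0.68 means
fingers are perceived 32% too short. The mixed model on the proximo-distal
component recovers the injected proximal drift:

```r
fit <- fit_component_lmm(errors, "vy")
tidy(fit)
#>   term                         statistic num_df den_df   p_value
#> 1 finger                           1.76       4  3013. 1.34e-  1
#> 2 type                          1884.         1  3013. 3.39e-320
#> 3 normalized_trial                27.1        1  3013. 2.02e-  7
#> ...
fit$trend$normalized_trial.trend
#> [1] -0.002675  # cm per normalized-trial unit; -0.003 was injected
```

`pca_errors(errors, "medio_lateral")` and `remove_pc1_and_recompute()`
implement the shared-bias decomposition: when the width overestimation is
carried by a common index→little-weighted lateral component across subjects,
removing PC1 returns the mean width ER to ≈ 1 (see the methods vignette,
`vignettes/handloc-methods.Rmd`, for the construction and its caveats).

`run_pipeline()` chains all stages and writes the tabular artifacts
(`errors.csv`, `consistency.csv`, `structure.csv`, `pca_loadings.csv`, fit
JSONs, `report.md`, and a checksum manifest).

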