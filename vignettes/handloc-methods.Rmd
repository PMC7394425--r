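---
title: "Methods: localization-error geometry, consistency and shared-bias decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localization-error geometry, consistency and shared-bias decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`handloc` analyses the trial-wise pointing errors of the hand Localization
Task (LT): where a participant perceives each of ten occluded hand
landmarks (five fingertips, five metacarpophalangeal knuckles) relative to
where the landmark actually is. This vignette documents the models, the
conventions, the synthetic-data engine, and the design decisions that were
genuinely open.

## The analysis frame and error vectors

All coordinates are put into a hand-aligned frame before anything else is
computed: coordinates are re-centred and rotated so the actual index–little
knuckle segment lies on the horizontal axis, with fingertips at positive y.
The transform is a proper rotation plus a shift, so it is an isometry —
error magnitudes are unchanged, directions are expressed in anatomical
terms.

Two conventions are fixed here and inherited by everything downstream:

- **Common origin.** The origin of the re-centred frame is a free choice
  that cancels in every error vector; we use the midpoint of the actual
  index–little knuckle segment. The midpoint makes the frame symmetric about the hand and keeps both
  knuckles equidistant from zero.
- **Sign semantics.** In the aligned frame of a left hand, negative vx is a
  lateral error (toward the shoulder line) and positive vx medial; negative
  vy is proximal (toward the body). Right hands are mirrored at error
  computation (vx negated), not at the coordinate level, so stored geometry
  stays physical while "lateral/medial" means the same thing for both
  hands. The direction is α = atan2(vy, vx) mapped to [0°, 360°): 0° is a
  perfectly medial error, 90° perfectly distal; the third quadrant
  (180°–270°) is proximal-lateral. A zero-magnitude error has no direction:
  such trials keep vx = vy = 0 for component analyses but are excluded from
  all direction statistics.

## Outlier exclusion

Within each subject × landmark cell, every trial's squared Mahalanobis
distance is computed from the cell's sample mean and unbiased (n − 1)
covariance, and trials above the χ²(2 df) 95th-percentile quantile
(`qchisq(0.95, 2)`, computed, not hard-coded) are excluded. The filter is
single-pass — one estimate, one sweep — because an iterative version would
change exclusion counts and make them irreproducible across
implementations. Cells with
fewer than 3 trials pass through unfiltered with a warning (the covariance
is undefined); an exactly singular covariance (identical or collinear
points) is an error naming the cell, since distances are then meaningless.
Under a bivariate-normal null the filter retains ≈95% of trials; the test
suite and the acceptance script verify this on large simulated samples.

## Angle consistency (ITPC)

Each defined error direction becomes a unit complex vector e^{iα}; the
inter-trial phase clustering index is the modulus of the arithmetic mean of
a set of such vectors, and the most frequent direction θ its argument. ITPC
is 1 exactly when all directions coincide and 0 under perfect cancellation
(θ is then undefined and returned as `NA`; the internal threshold is a
modulus below 1e-12).

Consistency is computed at four scopes: per subject pooling all landmarks
(within-subject overall), per subject × landmark, all vectors pooled
(between-subject overall), and per landmark × normalized-trial cluster.
Cluster c of n covers normalized trials in (100(c−1)/n, 100c/n] —
right-closed equal-width bins; the default n = 100 keeps per-cell counts
stable at typical LT sample sizes while resolving the session timeline. One ambiguity is documented rather than resolved: whether the
between-subject "grand average" pools trial vectors or averages per-subject
means. Pooling trials is the default (the more literal reading);
`pooling = "subject_means"` computes the alternative, and the two differ
exactly when trial counts are unbalanced across subjects.

Since ITPC distributions violate normality, group summaries are reported as
median ± interquartile range, and the inferential stage models consistency
with a Gamma log-link GLM (Wald χ², type III with sum-to-zero coding).
ITPC values of exactly 0 — possible only for degenerate cells — are clipped
to 1e-6 with a reported count, as the Gamma family needs a positive
response.

## Structure metrics and the shared-bias decomposition

Estimation ratios are perceived/actual: hand width from the index–little
knuckle distance (perceived positions are trial means), finger lengths from
tip–knuckle distances. ER < 1 is underestimation, ER > 1 overestimation; the inverse ratio would
silently flip those semantics, so the direction is fixed package-wide and
asserted in the tests.

The shared-bias analysis builds the subjects × 10-landmarks matrix of
per-subject mean error components (one matrix per axis), column-centres it,
and extracts principal components from the covariance structure —
unstandardized, so loadings stay on the cm scale and are comparable across
landmarks. The observation unit is the per-subject landmark mean:
trial-level PCA would be meaningless because each trial measures one
landmark only. PC1's sign is oriented so that the mean of its loadings
agrees in sign with the grand-mean error, preventing arbitrary flips across
runs.

**Removing PC1** is the one place where two defensible procedures give
different answers, and we implement both:

- `keep_mean = FALSE` (default): the full projection of each subject's
  mean-error row onto the PC1 axis is removed, mean included. If the shared
  bias is a nonzero-mean common shift — as an overlap bias toward the
  shoulder is — its average contribution to the perceived width disappears
  along with its between-subject variation. This is the variant under which
  a width overestimation injected purely through a common index→little-
  weighted lateral component is undone (mean width ER returns to ≈1), which
  is the substantive claim the decomposition exists to test.
- `keep_mean = TRUE`: the orthodox centred reconstruction
  (column means + Σ_{k≥2} score·loadingᵀ). Column means — hence grand-mean
  errors — are preserved exactly, and only the between-subject variation
  along PC1 is removed.

The untouched axis always keeps its original mean errors when perceived
positions are rebuilt.

The companion regression (`knuckle_slope_predicts_width()`) regresses each
subject's width ER on their lateral-error gradient across the four finger
knuckles (index→little coded 1–4, thumb excluded, per-subject slopes from
the mixed model or per-subject OLS). The quadratic consistency trend codes
all five knuckles 1–5 (thumb to little).

## Mixed models and GLMs

The component models are trial-level linear mixed models,
`v ~ finger × type × normalized_trial`, with by-subject random effects. Which
covariates deserve by-subject slopes is a genuinely open choice; we request
intercepts plus by-subject slopes for type and normalized trial — the
maximal structure the design supports — and fall back along a fixed ladder on convergence failure (drop the type
slope, then all slopes). The structure actually used is recorded in the fit
object; singular fits are accepted but flagged. Omnibus tests are type III
F tests with Satterthwaite degrees of freedom; estimated marginal means use
balanced factor margins with normalized trial held at its mean (or at a
caller-chosen value — recovery analyses evaluate at 0 so that a drift does
not shift the type means); post-hoc pairwise contrasts are
Bonferroni-corrected, with the comparison count reported. A Shapiro–Wilk
check on (up to 5000) residuals is attached as the residual-normality
diagnostic. The marginal normalized-trial slope, averaged over factor
margins, is reported separately since with interactions present the raw
coefficient is a reference-level slope.

## The synthetic-data engine

Raw trial-level LT data are rarely deposited, so the package carries a
generator that produces datasets with the statistical structure
the pipeline assumes; every stage is tested against it.

Per landmark, the generator takes a mean error magnitude |v| (cm), a most
frequent direction θ, and a target angle consistency r. Per subject it
draws one bivariate Gaussian offset (scale `subject_sd`) added to every
landmark's mean vector — inter-individual noise, a rigid translation of the
whole error field — then a per-landmark offset (scale `landmark_sd`). Each
trial draws a direction from a von Mises distribution centred on the
resulting cell direction with concentration κ solved from
I₁(κ)/I₀(κ) = r (uniroot on exponentially scaled Bessel ratios; r = 0 is
uniform, r = 1 degenerate, r > 0.9999 uses the asymptotic κ ≈ 1/(2(1−r))),
and a magnitude |M + N(0, `trial_sd`)|. The magnitude noise is *folded* at
zero rather than hard-truncated: truncation would put a point mass of exact
hits at the actual location, which is behaviourally unrealistic and creates
degenerate identical-point cells for the outlier filter. A drift adds
`drift_slope` × (normalized trial)/100 to vy. Trials are emitted in
randomized landmark order; one root seed spawns per-subject substreams, so
output is bit-for-bit reproducible.

Calibration facts the tests verify: the empirical ITPC of generated
directions converges to the requested r (±0.02 at 10,000 trials); zero
parameters give perceived ≡ actual exactly; an injected drift is recovered
by regression within ±20%; injected fingertip/knuckle proximal means are
recovered by the LMM stage within ±0.2 cm.

**Presets.** `preset_scenarios()` ships seven scenario presets spanning the
documented regimes — a baseline (fingertip errors ≈3.9 cm toward ≈240°,
consistency 0.98; knuckle errors small with an index→little lateral
gradient, consistency 0.90; proximal drift) and variants altering
magnitude, consistency or direction per landmark class — plus `null` and
`no_gradient` diagnostics. The numbers are approximations chosen once from
published group-level LT statistics (type-level marginal means of the
components, consistency medians) and then fixed; they are not a
transcription of any specific study's trial-level parameters. The preset
drift is −0.3 cm per 100 normalized trials: reported proprioceptive drifts
constrain it only qualitatively (clearly detectable in the component model,
yet too weak to change between-subject direction coherence over trial
clusters), and −0.3 satisfies both constraints, whereas a drift comparable to the knuckle error
magnitude itself would visibly rotate late-session error directions.

**What the generator does not emulate.** Subject offsets are rigid
translations, so the generator's between-subject PC1 has near-uniform
loadings; a shared component whose *weights vary across landmarks* (the
index→little-weighted overlap bias of the real data) is not produced by the
presets and is exercised by direct construction in the tests instead.
Consequently, passing tests show the pipeline's stages are correct, not
that real hands behave like the presets. Hand geometry is one template
shared by all simulated subjects; inter-individual hand-size variation,
digitization error from the photographs, and posture changes during the
session are out of scope (the pipeline starts from coordinate tables).

## Numerical choices and problem sizes

Angles are wrapped to [0°, 360°); degenerate directions are `NA` and
excluded from circular statistics. The alignment tolerates any rigid
displacement; its tests verify distance preservation to 1e-9 and
idempotence. PCA uses `prcomp` (SVD); reconstruction identities hold to
1e-9. The von Mises sampler is the Best–Fisher (1979) rejection algorithm.

The test suite runs its simulations at deliberately modest sizes — typically
6–20 subjects × 8–40 trials per landmark, 200 replicates for the type-I
error study at 8 subjects × 30 trials with the random-intercept model (the
null generator makes richer random structures singular) — chosen so the
whole suite completes in a few minutes while keeping Monte-Carlo error well
inside the asserted bands. The acceptance script uses 100,000 points for
the filter-calibration rate and 10,000 angle sets for the ITPC bound.

## Known limitations

- The Gamma GLM on ITPC treats (0, 1]-bounded values as Gamma-distributed;
  a pragmatic distributional choice that is an approximation near the upper
  bound, where fingertip consistencies concentrate.
- Satterthwaite denominator degrees of freedom are reported as the backend
  provides them; they need not match another implementation's df
  conventions, though omnibus conclusions are insensitive to this at the
  tested sizes.
- ITPC estimates from few vectors are positively biased (E ≈ √π/(2√n)
  under uniformity); between-subject landmark × cluster cells inherit this
  bias, which is why cluster counts should be compared only across cells of
  similar size.
- `validate_inputs()` checks schema and cross-references, not scientific
  plausibility (e.g. anatomically impossible hands pass validation).
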