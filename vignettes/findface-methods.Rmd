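---
title: "Measuring face discrimination thresholds with adaptive foraging charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring face discrimination thresholds with adaptive foraging charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(findface)
```

## The measurement problem

A morphable face model represents each face as a point in a space whose
axes are principal components of real face variation; coordinates are in
standard-deviation (σ) units of that variation, and Euclidean distance in
the space tracks perceived dissimilarity. `findface` estimates, for any
single component or pair of components, the distance `θ` at which two
faces are just reliably judged to be *different people*.

The task is a foraging chart: a grid of cells (default 3 × 3; 6° cells
separated by 3° gaps), each showing a pair of faces. Every pair has its
own fresh random identity — all 199 structural and 199 textural
coordinates drawn as independent standard normals — so no two cells look
alike and no face is ever repeated across charts, avoiding memory
artefacts. Within a pair the two faces share every coordinate except the
component(s) under test, where half of the test level is subtracted on
one side and added on the other (which side is random; with two target
components both move by the same signed amount). A random subset of cells
— a fraction drawn uniformly from (0.6, 0.8), i.e. 5, 6 or 7 of 9 cells —
are such targets; the rest are nulls with two identical faces. The
observer clicks every cell that appears to contain two different people.

For sessions with rotated faces, each face independently receives a yaw
drawn uniformly from ±5°, which removes pixelwise-identity cues and
forces identity-level judgment; the frontal default is `yaw_range = c(0, 0)`.

## Model and assumptions

Responses are modeled in signal-detection terms. Discriminability is a
saturating function of the test level `S`:

$$d'(S) = \frac{d'_{max}\,(S/\theta)^\gamma}
  {\sqrt{(d'^2_{max} - 1) + (S/\theta)^{2\gamma}}},\qquad
p(\mathrm{Yes}) = 1 - \Phi\!\left(\Phi^{-1}(1-F) - d'(S)\right).$$

* `θ` (σ units) — the threshold, defined as the level where `d' = 1`.
  Because the decision criterion is anchored by the false alarm rate, the
  yes-rate at threshold is well below 50% for small `F`
  (`p_yes(θ) ≈ 0.26` at `F = 0.05`).
* `γ` (dimensionless, default 1) — the transducer slope.
* `F` — the false alarm rate; the probability of "different" for two
  identical faces, and the model's value of `p(Yes)` at `S = 0` exactly.
* `d'max` (default 5) — the saturation ceiling of discriminability.

The model assumes statistically independent cells, no learning or
sequential dependence within a session, and a stationary criterion.

## The adaptive loop

1. **Chart 1** uses geometrically spaced levels (default 5 steps from
   0.5 σ to 16 σ, recycled over the drawn target count). The range is a
   design default chosen to bracket thresholds from the most to the least
   discriminable components a broad survey encounters (≈1–16 σ); it is
   configurable.
2. After every chart, the **cumulative** records for the component set
   are refit.
3. The next chart's target levels are placed at discriminability values
   equally spaced (endpoints included) over `d' = 0.1` to `4.5`, through
   the closed-form inverse of `d'(S)` at the current parameter estimates.
   Because the inverse diverges as `d' → d'max`, levels are capped at
   20 σ (configurable); capped placements are recorded in the audit log.
4. If a fit fails (too few distinct levels, or all-yes/all-no data), the
   previous chart's levels are reused, so a session never stalls.
5. The final threshold estimate is the fit after the last chart.

Component sets within a session run in a seeded interleaved order. All
randomness derives from one master seed through a documented splitting
scheme (`master·7919 + slot·104729 + chart·7 mod 2³¹−1`, one stream per
component-set × chart), so a session is bitwise reproducible and adding a
component set does not perturb the other sets' streams.

## Fitting: weighted least squares on binned proportions

Records are binned by exact level value (levels are discrete by
construction). The observed yes-proportions are fit by weighted nonlinear
least squares with weights `1/SE`, where `SE` is the *model-based*
binomial standard error `√(p(1−p)/n)` evaluated at the current fit and
iterated to its fixed point (IRLS). At the fixed point the weighted
least-squares normal equations coincide with the quasi-binomial score
equations, which both removes the infinite-weight problem at observed
proportions of 0 or 1 and makes the estimator far more efficient on
one-trial bins than observation-based weights.

`F` is estimated from the null cells as `(#FA + ½)/(#nulls + 1)` — never
exactly 0 or 1 — and held fixed during the fit; freeing it on the 2–4
nulls per chart is unstable, though `fix_false_alarm = FALSE` exposes the
free-`F` fit (with the level-0 bin included) for sensitivity analysis.

A session's three to four dozen binary cells cannot identify the slope:
unregularized fits drift to steep step-like solutions whose thresholds
migrate toward the 50%-yes level, well above the `d' = 1` definition. The
slope is therefore ridge-regularized toward the canonical unit slope,
with penalty weight proportional to the number of target records
(`slope_ridge`, default 0.45 per record ≈ a lognormal prior with SD 0.3
log-units at a typical session). Proportionality to the record count
keeps the penalty a fixed fraction of the data information and makes the
point estimate exactly invariant to duplicating every record. Hard bounds
`γ ∈ [0.25, 8]` remain as a backstop. Optimization is bounded
Levenberg–Marquardt on `(log θ, log γ)`, multi-started from the minimum,
geometric mean and maximum tested level; the lowest penalized deviance
wins, ties broken toward the smaller threshold.

## Simulated observers

`simulated_observer()` closes the loop for validation. Responses are
Bernoulli draws from the same model, with per-component true parameters,
an optional lapse rate `λ` (a 50:50 random response with probability λ),
and three combination rules for multi-component pairs:

* `euclidean` (default): per-component differences combine as Euclidean
  distance *before* the transducer, so two equally detectable components
  changed together reduce the threshold by exactly √2 — the classical
  probability-summation benchmark. With heterogeneous per-component
  parameters the first target component's channel is used; the benchmark
  presumes a shared `θ, γ`.
* `single`: extra components are ignored — the no-facilitation null.
* `dprime_quadrature`: channel d′ values combine as a root sum of squares
  *after* the saturating transducer; near threshold this yields a ratio
  slightly below √2 (≈1.43 at `d'max = 5`). The literature attributes the
  effect to Euclidean face-space distance, so `euclidean` is the default
  benchmark; neither mechanism is asserted as ground truth.

What the generator deliberately does not emulate: image-computable
responses (no pixels are rendered), learning, fatigue drift, or
criterion shifts. Passing recovery tests therefore demonstrates the
correctness and calibration of the *algorithm*, not the ecological
validity of real-observer data.

## Analyses

* `summation_analysis()` compares single-component against
  combined-component thresholds. Each combined set {i, i+1} is referenced
  against the mean of singles i and i+1 (an option uses the minimum
  instead); participant-level means feed a paired t-test and the
  per-participant single:combined ratios are tested against √2. The
  analysis is scale invariant.
* `bland_altman()` assesses test–retest agreement: bias (mean of
  test − retest), 1.96·SD limits of agreement, a one-sample t-test on the
  differences, and a proportional-bias check by OLS regression of
  differences on pairwise means with a t-test on the slope (the standard
  check; the exact historical procedure is not prescribed anywhere, so
  ordinary least squares was chosen).
* `group_compare()` is a Student t (pooled variance when unpaired) with
  Cohen's d (pooled-SD d unpaired, difference-SD d paired), matching the
  df conventions of classical two-sample threshold comparisons.

## Numerical choices and degenerate inputs

* `F` is clamped to `[10⁻⁴, 1 − 10⁻⁴]`; `p_yes(0)` returns `F` exactly
  (assigned, not computed through the Φ round-trip, which loses a ulp).
* `invert_dprime` signals a saturation error at `d ≥ d'max`; the engine
  additionally caps levels at 20 σ.
* Fits require ≥ 1 null and ≥ 2 distinct positive levels, else a flagged
  non-converged fallback is returned and the engine reuses the previous
  levels. All-yes or all-no target data likewise fall back.
* Zero-variance inputs in the analyses are handled explicitly: identical
  test/retest gives bias 0 with degenerate limits; constant nonzero
  differences give a certain-bias result; paired comparisons with zero
  difference variance are an error.
* Chart-spec JSON serializes coordinates with 17 significant digits and
  record CSVs use `%.17g` levels, so both round-trips are lossless.

## Validation sizes and known limitations

The test suite validates the pipeline end-to-end with simulation sizes
chosen to match the method's intended study design: a 10,000-chart
target-count census; a summation cohort of 8 Euclidean-rule observers ×
(10 single + 10 combined) sets × 4 charts; 200 closed-loop sessions per
true threshold in {2, 4, 8} σ; and an 11-participant × 10-component
test–retest null calibration of the Bland–Altman procedure.

The main known limitation is single-session precision. A 4-chart session
contains ~24 target and ~12 null binary cells; information analysis of
this design shows the median relative error of any estimator of `θ` is
bounded below by roughly 16% even with the slope and false alarm rate
known, and by roughly 24% once `F` must be estimated from the session's
own nulls — the dominant noise source, since the criterion `Φ⁻¹(1−F)`
shifts the whole curve. The closed-loop recovery test measures ~22–31%
median error with a mild upward median drift (the threshold sits at a
yes-rate of ~0.26, so sparse data bound it more tightly from below than
from above). Single-session thresholds should accordingly be read as
coarse (±~25%) estimates; averaging across components or sessions, as the
summation and test–retest analyses do, is where the method's precision
lies. The summation ratio, being a ratio of means over 80 session pairs,
recovers √2 to within a few percent.
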