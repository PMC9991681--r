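---
title: "Food-environment access and spatial food-insecurity risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food-environment access and spatial food-insecurity risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodaccess)
```

This package implements a complete epidemiological workflow for asking
whether patients who screen positive for food insecurity live further from
healthful grocery stores than food-secure patients, and for mapping where
food-insecurity risk is spatially elevated. Because patient-level clinical
and geocoded data of this kind cannot be shared, the workflow runs
end-to-end on a seeded synthetic city whose statistical structure matches
the study conditions the analysis assumes. This vignette explains each
model, its assumptions, the tunable parameters, and the design decisions
where the methodology was genuinely open.

## The scientific setting

Food insecurity — limited or uncertain household access to adequate food —
is screened in clinical settings with the two-item Hunger Vital Sign; a
patient answering either item affirmatively is classified food insecure.
The food environment side is measured with the Nutrition Environment
Measures Survey in Stores (NEMS-S), which scores each full-line grocery
store for availability, price, and quality of healthy options. The analysis
links the two through geographic exposure metrics, asks whether exposure
differs by insecurity status after socio-demographic adjustment, whether
area vehicle availability modifies the association, and where in the study
window insecurity risk is elevated.

## NEMS-S scoring

Availability items are scored 0–6 each, price comparison items −1–2 each
(negative when the healthier option costs more), and fresh-produce quality
is a single 0–6 rating. Sub-scores are item sums; the total is the sum of
sub-scores. The default instrument has 5 availability and 9 price items,
which reproduces the published sub-score ranges exactly: availability 0–30,
price −9–18, quality 0–6, total −9–54. The canonical instrument's full item
list is not needed for any downstream quantity, so item counts are
configurable with these defaults; validation errors name the offending item
index. `score_stores()` is the single source of score truth: the synthetic
generator samples raw item responses and derives every store score through
it.

## The synthetic city

`generate_city()` draws, deterministically from one seed:

* **Tracts** — a regular `n_tracts_x` × `n_tracts_y` grid over a planar
  rectangle in miles (default 12 × 10 miles, 120 tracts). Coordinates are
  abstract planar miles with straight-line distance; no geodesy. Tract
  covariates (median income, poverty, unemployment, uninsured, carless, and
  public-assistance percentages) are smooth spatial fields: a baseline
  typical of a high-poverty urban area, a hotspot-intensity term oriented so
  that disadvantage tracks insecurity (lower income, higher rates), a
  low-frequency random surface, and white noise, clamped to valid ranges.
* **Patients** — default 1100, uniform locations, with age, sex, race,
  marital status, and BMI drawn from plausible screening-cohort margins.
  The binary outcome follows a logistic model
  `logit(p) = logit(0.31) + centred(hotspot bumps + covariate terms)`:
  Gaussian hotspot bumps `bump · exp(−d²/2r²)` (three by default) plus
  per-covariate log-odds terms (age −0.02/yr, married −0.5, BMI +0.01).
  Centring the linear predictor keeps the marginal prevalence near the 31%
  target; over seeds the realised prevalence averages ≈ 31.8% (mild Jensen
  inflation), well within the ±3-point tolerance the generator promises.
* **Stores** — default 75. Integer total-score targets are drawn from a
  truncated normal on [16, 35] whose *parent* moments are solved
  numerically so the truncated distribution itself has mean 27 and sd 5
  (truncation otherwise shrinks the sd below target). Most stores (72/75 in
  expectation) get the top quality rating of 6, matching the near-constant
  quality reported for real store audits. Item responses are sampled and
  then nudged one step at a time until the scorer reproduces the target
  total, so the item-level data stay consistent with the scores.

The joint distribution of patient covariates is a plausibility choice — the
study design only fixes group-comparison directions, not a joint law — and
is documented in `city_config()`. What the generator does *not* emulate:
real street geography, spatially clustered residences, measurement error in
geocoding, informative (MNAR) missingness, and within-tract covariate
heterogeneity. Tests passing on this synthetic city therefore validate the
statistical machinery, not any claim about a real city's food environment.

`inject_missingness()` masks covariate cells MCAR or MAR-on-age (masking
probability increasing in age, rescaled to the marginal rate). Default
rates: marital status 20%, BMI 15%, race 10% — chosen to emulate the high
EMR missingness that motivates imputation. The outcome, coordinates, and
tract link are never maskable.

## Exposure metrics

Distances are the full patient × store matrix (1100 × 75 = 82 500 at
default scale), Euclidean by default. A network metric over a weighted road
graph is provided; on layouts where routes are straight lines the two agree
exactly, which mirrors the empirical finding that walking and driving
distances can be interchangeable and justifies the single abstract metric.

For radii 0.5, 1, and 2 miles the package reports the maximum
("healthiest") and mean ("typical") NEMS-S total, availability and price
scores over stores in the **closed** ball (a store exactly at the radius
counts; the convention is arbitrary but fixed and boundary-tested), plus a
presence flag. When no store lies within the radius the summaries are
missing, *not* zero — those patients are excluded from that radius's
continuous models, with counts reported.

The access curve is the running maximum of store scores by distance (ties
collapse to their maximum; value 0 before the first store). The
accessibility AUC integrates this curve over `[0, horizon]` (default 10
miles). Because the curve is piecewise constant the integral is computed
exactly as a sum of step areas — the refinement limit of the trapezoid rule
— which removes grid-resolution nondeterminism; the test suite checks
agreement with a literal fine-grid trapezoid oracle. The value of the curve
before the nearest store and the integration horizon are conventions the
AUC definition leaves open; setting the pre-store value to 0 and using a
fixed horizon preserves the intended ordering (patients with nearer,
better stores get strictly larger AUC) and both are configurable.

## Multiple imputation and pooling

`impute_covariates()` is fully conditional specification: each incomplete
variable is regressed on all others in the working table and its missing
cells are replaced by draws, cycling (default 5 imputations × 10 cycles;
the analysis drivers use 5 cycles, which the chain-mean diagnostics show is
ample at these missingness rates). The default base learner is a random
forest whose imputed values are drawn from *terminal-node donors*: for each
missing row a random tree is chosen and one observed response co-landing in
the same leaf is drawn. Donor draws, rather than node means, propagate
predictive uncertainty; the named method leaves the draw scheme open and
this is the standard resolution. Gaussian-linear and predictive-mean-
matching learners are available for speed and for continuous-margin
checks. The outcome and the presence indicators enter as predictors; fully
observed variables are predictors only (tract covariates are complete by
construction, so imputing them is moot).

`pool_estimates()` applies the standard combining rules: pooled estimate
`Q̄ = mean(Q_k)`, total variance `T = W̄ + (1 + 1/m)B` with `W̄` the mean
within-imputation variance and `B` the between-imputation sample variance.
Degrees of freedom use the Barnard–Rubin small-sample adjustment (the
large-sample rule is a `dfcom = Inf` special case) — the right choice at
m = 5. Identities tested exactly: `B = 0` degeneracy, the hand-computed
`T = 7/3` example, and no-missing-data stacks pooling to precisely the
complete-data fit.

## Association models

Descriptives use Welch t-tests and chi-squared tests (continuity correction
off by default, including 2 × 2 tables — a documented flag). Store-tract
relationships use Pearson correlations with t-based p-values. Significance
is prespecified at 0.05 throughout with no multiple-testing correction,
matching the analysis design this package implements; with ~84 fitted
models that is a real limitation and is flagged here deliberately.

Exposure models regress each exposure on insecurity status: linear for
continuous summaries and the AUC (estimates are mean differences, insecure
minus secure), logistic for presence indicators (estimates are odds
ratios). Adjusted models add age, marital status, median household income,
poverty, unemployment, vehicle non-availability, and public-assistance
rates. The 2-mile presence model is refused by default because almost no
patient lacks a store at that range, making the logistic fit unstable; an
override flag exists. Separation in any logistic fit is detected and
reported on the result object rather than silently ignored.

Effect modification by area vehicle availability uses a product term
`insecure × high-stratum` for the interaction p-value plus subgroup refits
for stratum estimates (dropping the vehicle rate from the stratum
adjustment set, since stratification conditions on it). The high stratum is
tracts at or above (closed comparison) the third quartile of the carless
percentage by default, or a fixed threshold such as 17% when supplied. All
per-imputation fits are pooled by Rubin's rules.

## Spatial relative risk

The risk surface is `ρ̂ = log f̂ − log ĝ` with `f̂` the case (food-insecure)
and `ĝ` the control density, estimated by the *symmetric adaptive* method:

1. one pilot density is fitted to the pooled case + control points with a
   fixed bandwidth (bivariate normal-scale rule per axis,
   `min(sd, IQR/1.34) · n^(−1/6)`, geometric-mean combined);
2. Abramson bandwidths `h_i = h0 · f̃(x_i)^(−1/2) / γ` rescale a global
   bandwidth by inverse-root pilot density, with `γ` the geometric mean of
   `f̃^(−1/2)` over the *pooled* sample — so cases and controls share one
   pilot and one normalisation (the "symmetric" contract), which stabilises
   the ratio and makes the bandwidths invariant under case/control
   relabelling;
3. both densities use a Gaussian product kernel, evaluated on the grid via
   separable factor matrices, and are renormalised to unit mass over the
   study window. No per-point boundary correction is applied by default
   (the window renormalisation absorbs aggregate edge loss); the
   normal-scale bandwidth was preferred over the larger Terrell
   oversmoothing rule after direct comparison — it gave better hotspot
   localisation (argmax containment 0.93 vs 0.85 over 60 planted-cluster
   replicates) and better null calibration (mean per-replicate KS 0.09 vs
   0.14).

A density floor of `1e-12 × max(max f̂, max ĝ)` is applied to both
densities before the logs. Using one symmetric floor (rather than a floor
tied to `ĝ` alone) keeps the estimator exactly antisymmetric under label
swap — a tested identity — and floored cells are flagged and excluded from
contouring.

Significance uses Monte-Carlo tolerance contours: case/control labels are
randomly permuted (default 999 draws; the drivers use 199), densities and
`ρ̂` recomputed — the bandwidths need no recomputation, a direct payoff of
the symmetric contract — and each cell's upper-tail p-value is
`(1 + #{ρ̂_perm ≥ ρ̂_obs})/(B + 1)`. Permutation contours were chosen over
asymptotic ones because they are assumption-free and testable at desk
scale. Contours trace the `p = α` level set by marching squares with
sub-cell linear interpolation (`grDevices::contourLines`). Under the null
the per-cell p-values pool to near-uniform (KS < 0.1 over 50 replicates at
a 32 × 32 grid in the acceptance suite), and a 3× oversampled disc is
intersected by a significant contour in ≈ 98% of replicates at
n = 300/300 with 199 permutations.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; the pipeline derives
  named substream seeds from one global seed, so a single integer
  reproduces every artifact. Identical configurations give byte-identical
  CSV outputs for exact stages.
* Problem sizes in the test and acceptance suites were scaled for a desk
  run: recovery experiments use one full-size cohort (n = 1100, m = 5
  imputations, 5 cycles, 50 trees), spatial calibration uses a 32 × 32
  grid with 99–199 permutations, and null-size calibration uses 1000
  replicates. These sizes are stated here as the package's own choices.
* Degenerate inputs fail loudly: infeasible score targets, 100%-missing
  variables, constant modifiers, empty strata, zero bandwidths,
  disconnected road-graph snaps, and out-of-scale items all raise errors
  that name the offending quantity.

## Known limitations

* Uniform patient locations understate real residential clustering; the
  spatial module is validated on planted clusters instead.
* Ecological covariates are attributed to patients by tract of residence;
  any individual-level reading of their coefficients risks the ecological
  fallacy, exactly as in the motivating study design.
* The random-forest learner's donor draws approximate, but do not match,
  a fully Bayesian imputation; coverage of pooled intervals is verified
  empirically (≥ 85–95% in the suite) rather than guaranteed.
* MNAR missingness and congeniality questions are out of scope.
* No multiple-testing correction is applied across the model grid, by
  design parity with the analysis this package reproduces.
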