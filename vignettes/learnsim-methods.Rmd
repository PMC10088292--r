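---
title: "Simulating clinical cohorts with hierarchical learning effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating clinical cohorts with hierarchical learning effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why this generator exists

Methods that try to disentangle the intrinsic safety signal of a novel
treatment (a device, procedure, or drug) from the transient excess risk of
*experiential learning* — providers and institutions getting better as
their treatment-specific case counts grow — cannot be validated on real
data, where the ground truth is unobservable. `learnsim` generates
synthetic patient populations in which both kinds of risk are injected
with known magnitude, so that detection and attribution algorithms can be
benchmarked against a latent truth table.

The pipeline is hierarchical and modular:

1. **Cohort structure.** Institutions receive provider counts from a
   user-specified mixture (largest-remainder apportionment, so an even
   split is exact when divisible). Each provider draws a volume class and
   then an integer annual caseload, independently per active year, from
   that class's inclusive range; bimodal high/low mixtures are the typical
   configuration. Entry is either simultaneous (all providers active from
   year 1) or annual (`ceiling(P/2)` in year 1, the rest round-robin over
   later years — the remainder rule is ours, since "evenly divided" leaves
   it open). The total sample size is *implied* by the roster, not set
   directly.
2. **Feature synthesis.** Patient features with non-normal, correlated
   marginals are produced by an iterative rank-substitution algorithm
   (below).
3. **Treatment assignment.** A logistic model with user odds ratios and an
   intercept calibrated so the mean assignment probability equals the
   target prevalence; Bernoulli draws produce arms; patients are shuffled
   within each year and treatment-specific case-series numbers `CN_prov`
   and `CN_inst` are read off cumulatively.
4. **Patient/treatment risk.** `p_pt` from a second logistic model whose
   intercept is pinned by the target population event rate.
5. **Learning effects.** Up to four learning curves (provider/institution
   x novel/reference), each solved from (form, magnitude, speed).
6. **Outcomes.** The three risks combine through
   `p_noevent = (1 - p_pt)(1 - p_prov)(1 - p_inst)`, `p_event = 1 -
   p_noevent`; outcomes are Bernoulli draws.
7. **Finalization.** Optional label noise, MCAR masking, omitted
   variables — applied to the public file only; the truth file keeps every
   latent quantity.

## The feature-synthesis loop

Given a target correlation matrix and one marginal per (indicator-coded)
column — an empirical pool from a reference data cube, or a parametric
family materialized as a large pool (`max(10n, 10000)` values; parametric
pools use quantile grids so the pool itself carries no sampling noise) —
the loop:

1. draws `n x k` standard normals under a working *intermediate*
   correlation matrix (initialized at the target);
2. replaces each column by a sorted bootstrap resample of its pool,
   matched by the rank of the normal deviates (so marginals are exact up to
   resampling and no normality is assumed);
3. measures the realized correlation of the substituted data, adds the
   residual (target minus realized) to the intermediate matrix, and repairs
   it to positive definiteness by eigenvalue clipping at `pd_floor = 1e-6`
   followed by rescaling to unit diagonal;
4. keeps the intermediate matrix with the smallest root-mean-square
   residual (RMSR) and stops after `max_iterations = 50` or `patience = 10`
   iterations without improvement, then generates the returned matrix with
   the best intermediate.

The defaults mirror common practice for this family of algorithms and are
exposed as `feature_spec()` controls, not asserted as canonical. Ties in
the rank matching are a non-issue: ranks are taken on the continuous
normal deviates, and discrete marginals land on their order statistics.

Categorical features travel through their indicator coding (one 0/1
column per level, correlations estimated or defaulted to the multinomial
within-feature value) and are decoded to a single level by an argmax that
prefers indicators set to 1 and breaks ties by the threshold-shifted
latent deviate. Decoding blurs indicator correlations somewhat — targets
on categorical indicators are met more loosely than on continuous or
binary columns, which our tests reflect.

Constant cube columns stay as marginals but are dropped from correlation
targets (their correlation is undefined); a target matrix that is not
positive definite and cannot be repaired without moving some entry by
more than 0.05 is an error naming the offending eigenvalue.

## Calibration

Both intercepts solve `mean(plogis(alpha + lp)) = target` on the realized
population by monotone root-finding (`uniroot` plus Newton polishing, to
within 1e-10). Calibrating on each generated dataset — rather than
analytically on the population — means the *specified* rate is met exactly
in expectation over probabilities, while realized draws scatter around it
exactly as estimation from finite samples should. Continuous features
enter both linear predictors standardized by their generating pool's mean
and SD, so an odds ratio on a continuous feature reads "per 1 SD"; the
raw-unit alternative is recoverable by rescaling, and this choice makes
magnitudes comparable across features. The outcome intercept
is calibrated after treatment assignment, including the treatment term,
so the target is the whole-population rate.

## Learning curves

Every form satisfies the same two-point contract: the value at case 1
equals the initial magnitude `m`, and the value at the mastery case
`speed` has declined to 5% of `m` — our reconciliation of "declines to 0"
with mastery defined as 95% of asymptotic performance. Beyond `speed` the
curve is truncated to exactly 0, and the truncation case is recorded so
benchmarked methods can be scored against it.

| form | curve | solved parameters |
|---|---|---|
| exponential | `b0 * exp(-b1 * CN)` | `b1 = log(20)/(speed-1)`, `b0 = m * exp(b1)` |
| power | `b0 * CN^(-b1)` | `b0 = m`, `b1 = log(20)/log(speed)` |
| reciprocal | `b0 * b1/(CN + b1 - 1)` | `b0 = m`, `b1 = (speed-1)/19` |
| weibull | `b0 * exp(-(b1 (CN-1))^shape)` | `b0 = m`, `b1 = log(20)^(1/shape)/(speed-1)` |

The exponential and power forms follow the standard parameterizations of
the learning-curve literature; the reciprocal and Weibull forms are our
conventions satisfying the same boundary contract (the Weibull `shape`
defaults to 1.5 and is user-settable). A *relative* magnitude is resolved
per dataset as the specified fraction of the mean `p_pt` among patients on
the affected arm, anchoring learning risk to realized patient/treatment
risk.

The three risk components are combined as independent — a deliberate
simplification: no covariance between learning pace and patient
complexity, or between levels. Evaluations of algorithms under this
assumption may be optimistic relative to real data where case mix and
institutional context shape learning.

## Randomness and reproducibility

One master seed drives everything; each stage (roster, features,
treatment, shuffle, outcome, noise, missingness) uses a deterministically
derived substream. The same `(config, seed)` pair reproduces a dataset
byte-for-byte, and changing one stage's options cannot perturb another's
draws — e.g. adding missingness leaves treatment assignment untouched,
which the evaluation harness exploits to vary one stage at a time. The
within-year shuffle is a single global permutation per year (not scoped to
institutions), inducing random interleaving of case series at both
hierarchy levels. At outcome time one uniform vector is drawn and compared
against both `p_event` (the outcome) and `p_pt` alone
(`outcome_pre_learning`), so pre-learning event rates are well-defined and
maximally coupled to the final outcomes.

Finalization uses exact-count semantics by default: exactly
`round(fraction * N)` labels are flipped and `round(fraction * n * k)`
feature cells masked, selected uniformly. "A specified proportion" reads
most naturally as a fixed fraction, and exact counts make the behavior
sharply testable; independent per-unit Bernoulli selection is available
behind `exact_counts = FALSE`. Masking is MCAR only — informative
missingness is out of scope.

## The synthetic reference cube

`make_reference_cube()` emits a fully synthetic 35-feature stand-in for an
EHR-derived ICU data cube: 20 continuous features (vitals, labs, lengths
of stay; several right-skewed lognormal/gamma marginals, one left-skewed
oxygen-saturation marginal) and 15 binary comorbidity/intervention flags,
tied together by a Gaussian copula with a documented block structure
(renal markers with kidney disease, lactate/pressors/ventilation with
sepsis, chronic disease with age, and so on). No real patient data enters
its construction; it exists so the cube-input path
(`spec_from_cube()` -> `simulate_features()`) can be exercised and
evaluated end to end. Real data cubes are supplied as CSVs with a typed
`name:type` header via `read_cube()`.

## The evaluation harness, and what it shows

`summarize_dataset()` refits a *correctly parameterized* logistic model
(the features carrying outcome odds ratios, plus treatment) and reports
realized prevalence, realized pre-learning event rate, and the treatment
OR with a Wald 95% CI. `coverage_experiment()` runs a factorial grid of
configurations; `feature_containment_experiment()` checks how often a
reference feature mean falls inside the synthesized sample mean's 95% CI;
`compare_features()` tests marginal fidelity (Wilcoxon for location,
Levene for spread, chi-squared for discrete features, Holm-adjusted as one
family per comparison); `case_series_curve()` fits binomial penalized
regression splines (`mgcv::gam`) of outcome on case number with pointwise
Wald bands, and `stabilization_case()` reports the first case number after
which the with-learning curve no longer exceeds the upper limit of the
no-learning band (one-sided, because learning risk is non-negative; dips
below the band are noise).

Problem sizes are desk scale by design: the packaged study runs a
162-cell grid (treatment OR x prevalence x event rate x 5-30 institutions
x 2-4 years) with a handful of replicates per cell — roughly 650 datasets
of between about a thousand and seventeen thousand patients — rather than
a tens-of-thousands-of-datasets factorial, and a compact three-feature
specification in grid cells where the quantity of interest is parameter
recovery rather than feature fidelity (feature-fidelity experiments use
the full 35-feature cube). The stabilization measurement pools twelve
replicate dataset pairs: a single dataset's band is too wide to localize
the mastery point, and pooling is consistent (as the band tightens the
detected point approaches the true truncation case).

What passing these checks shows: the generator's realized parameters
track their specifications, calibration identities hold to numerical
tolerance, and injected learning produces the decline-then-stabilize
signature at the configured mastery point. What they do not show: that
synthetic cohorts reproduce the messiness of real clinical data —
informative missingness, non-random patient-provider sorting,
provider-level covariates, learning correlated with case mix — all of
which are explicitly outside this generator's scope.

## Known limitations

- Learning curves are monotone non-increasing; plateau-dip or forgetting
  shapes are not representable.
- Categorical indicator correlations are approximate after decoding.
- The smallest practical cohorts (a few hundred patients) estimate odds
  ratios with high variance; specification-vs-realization agreement is a
  large-sample statement, and below roughly 3,000 observations users
  should check fidelity before benchmarking.
- Providers practice at exactly one institution, and patients are
  randomized to providers.
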