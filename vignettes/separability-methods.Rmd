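---
title: "Methods: split-half residual separability and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-half residual separability and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physep)
```

## The question and the procedure

Individual-differences designs ask whether two tasks tap the same underlying
ability by correlating performance across people. The harder question this
package addresses is *separability*: after removing the variance in a
physical-prediction measure (the unstable-towers task) that spatial reasoning
and working memory can account for, is anything systematic left?

The test is a split-half residual correlation:

1. Split the 48 towers trials into two halves at random, balanced within
   every stratum (block count x landing side), so both halves contain the
   same mix of trial types.
2. Compute each participant's accuracy on each half.
3. Regress each half's accuracy on two covariates computed from the *full*
   data of the other four tasks: a combined spatial score (mean of
   paper-folding and mental-rotation accuracy) and a combined working-memory
   score (mean of the two complex-span accuracies). Only the towers trials
   are split; the covariates cannot be half-specific and are deliberately
   shared between the two models.
4. Correlate the two residual vectors across participants (Pearson).
5. Assess significance by permutation: shuffle the participant
   correspondence between the residual vectors 10,000 times and report the
   proportion of shuffled correlations strictly larger in absolute value
   than the observed one (two-tailed; ties do not count against the observed
   value).

The logic: binomial trial noise is independent between halves, so any
correlation between the residuals must come from systematic between-person
variance that the covariates failed to capture.

## Scoring rules and chance floors

Accuracy is always correct units over scheduled units: towers /48,
paper folding /20, mental rotation /48 (per selection — choosing one of an
item's two correct options earns partial credit), each working memory task
/24 span trials. A span trial is correct only under exact-set recall (all
target positions selected, none extra); recall order is ignored. The chance
floors differ by response format and are computed analytically:
1/2 (towers; and mental rotation, where a uniformly chosen pair of the four
options contains on average one of the two rotated targets), 1/5 (paper
folding), and 2^-12 ≈ 0.024% (working memory: a uniform subset of the 12
grid cells must equal the target set; the probability does not depend on the
set size).

Participants are screened once, on the full cohort, using the secondary
tasks embedded in the complex spans: anyone more than `k_sd = 5` SD below
the cohort mean on symmetry-judgement or lexical-decision accuracy (an OR
rule over the two measures, each with its own SD) is excluded. Thresholds
are not recomputed after exclusion — single-pass screening is idempotent by
construction, and a zero-SD measure excludes nobody. The OR rule and the
per-measure SDs are design choices: they are the most conservative reading
for data quality, and they treat the two secondary measures as the distinct
checks they are.

## Statistical machinery

All correlations are Pearson; degenerate inputs (constant vectors, n < 3)
raise errors rather than NaN. Permutation tests shuffle exactly one
variable's participant labels, equivalent to shuffling the pairing. The
p-value uses strict inequality with resolution 1/n_iter; an add-one
smoothed option exists but is off by default, matching the strict
definition above.

OLS models are compared two ways, which agree by construction:

* `AIC = n ln(RSS/n) + 2(k + 1)`, the Gaussian profile-likelihood form, with
  the +1 counting the error-variance parameter. Evidence ratios
  `exp(|ΔAIC|/2)` depend only on AIC differences, so the constant convention
  cancels in every comparison of models fit to the same data.
* The nested F test `F = ((RSS_r − RSS_f)/Δk) / (RSS_f/(n − k_f))` with
  `(Δk, n − k_f)` degrees of freedom. The identity
  `ΔAIC = −n ln(1 + Δk F/(n − k_f)) + 2Δk` ties the two together and is
  asserted in the tests.

## The synthetic cohort generator

Because the battery's raw data are external, the package ships a generator
whose statistical structure matches what the analysis assumes, with ground
truth exposed for recovery tests. Three standard-normal latent factors:
spatial ability S, working memory W (correlated at `latent_corr`, default
0.3), and a physics-unique factor U independent of both. Each task's true
ability is a linear combination `θ_task = loadings · (s, w, u)`; by
construction only the towers task may load on U, so "unique variance" is
unambiguous: the partial variance of towers θ given (s, w) is exactly
`loading_U² · sd_U²`.

Unit-level correctness follows a guessing-floor logistic (3PL-style)
response model, the simplest family with the required features — per-task
chance floors, graded above-floor performance, heterogeneous item
difficulty:

P(correct) = c_task + (1 − c_task) · logistic(θ_task − b_item),
b_item ~ N(mean_task, sd_task), drawn once per cohort.

Defaults and why:

* `n_participants = 100`, schedule as in the battery design (48/20/48/24/24
  primary units, 132 secondary judgements per WM task).
* Towers loadings (S, W, U) = (0.45, 0, 0.6); spatial tasks load 1.0 on S;
  WM tasks 0.6 on W. These were chosen, once, so that simulated accuracy
  means/SDs and the split-half and intercorrelation pattern sit in the
  realistic range for this battery (towers ≈ 78% ± 9%, split-half r ≈ 0.5,
  WM pair r ≈ 0.6).
* Item difficulty spreads (towers 0.8, spatial 1.0, WM 0.5 on the logit
  scale) give items spanning near-chance to near-ceiling; the towers
  difficulty location (−0.32) puts mean accuracy near 79%.
* WM set size (3–8) shifts item difficulty linearly (`wm_setsize_slope`,
  default 0.25 per step), so longer spans are harder; there are no published
  per-set-size accuracies to calibrate the slope against, so it is a knob,
  not a fitted value.
* Span trials are simulated as one Bernoulli unit each rather than
  per-element recall, because scoring only uses exact-set trial correctness;
  the two selections of a mental-rotation item are conditionally independent
  given θ, because scoring is per selection.
* Secondary judgements are Bernoulli at 0.95, with an option to plant
  low-performing participants for screening tests.

What the generator does **not** emulate: response times, trial-order and
fatigue effects, within-item dependence beyond θ, non-normal ability
distributions, and any actual physics of the tower stimuli. Passing recovery
tests therefore show the *pipeline* is correct and calibrated under the
assumed measurement model — not that the model is true of real participants.

## Calibration properties and their limits

Two properties of the residual-separability procedure deserve honesty:

* **Power.** With the default planted unique factor (0.6 latent-SD) and the
  battery schedule at n = 100, the procedure detects the factor
  (r_resid > 0, permutation p < .05) in well over 90% of replicate cohorts.
* **Null calibration and covariate attenuation.** With the unique loading at
  zero but the finite default schedule, the covariates are error-laden
  proxies of S and W; regression cannot fully remove the shared latent
  variance, the leak is common to both halves, and the false-positive rate
  exceeds the nominal 5%. This attenuation bias is inherent to
  residualizing on noisy covariates, not an implementation artifact. The
  null-calibration simulations therefore enlarge the predictor-task trial
  counts (x10), driving covariate reliability toward 1, where the false
  positive rate falls within binomial bounds of 5%. Interpreting a
  significant residual correlation on real data requires the covariates to
  be highly reliable — or a correction for attenuation, which is out of
  scope here.

A related structural limit: with towers loading positively on S and
corr(S, W) > 0, the model cannot simultaneously produce zero towers–WM
correlation and positive spatial–WM and towers–spatial correlations, so the
simulated intercorrelation pattern approximates, rather than reproduces, an
empirical pattern in which towers–WM correlations vanish. A suppressor
structure would be needed; we prefer the transparent three-factor model.

## Numerical and procedural choices

* One split plan per analysis call by default, mirroring a single randomized
  split; `n_plans > 1` averages r over independent plans for stability (the
  permutation p then refers to the first plan).
* The towers split stratifies jointly on block count x landing side (strata
  of 4); odd strata put the extra item in a random half.
* Item-level splits halve the participants without stratification.
* Spearman–Brown `2r/(1+r)` is always reported alongside, never substituted
  for, the raw split-half r.
* All randomness flows from explicit integer seeds; every seeded function
  saves and restores the global RNG state, and a pipeline report is
  byte-reproducible from its recorded seed.
* Degenerate inputs error loudly: constant vectors in correlations,
  rank-deficient designs, perfect fits (AIC undefined at RSS = 0), singleton
  strata, incomplete schedules (named by participant and task).

## Problem sizes used in the verification suite

Monte-Carlo checks use sizes chosen to make their tolerances meaningful at
desk scale: 50,000 draws for latent-covariance calibration (±0.02);
cohorts of 2,000 participants for the analytic split-half reliability
comparison (±0.03, with the analytic value from numerical integration of
the response model over the ability distribution); 500 null simulations of
n = 200 for type-I calibration of the permutation test (99% binomial
bounds); 100 replicate cohorts each for the power and null branches of the
residual-separability recovery study; exhaustive enumeration (120
permutations, 4096 subsets, 6 option pairs) wherever the space is small
enough to enumerate.
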