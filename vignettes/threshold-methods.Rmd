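---
title: "Deriving plasma Aβ42/Aβ40 positivity thresholds: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving plasma Aβ42/Aβ40 positivity thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abratio)
```

## The problem

The plasma Aβ42/Aβ40 concentration ratio falls when amyloid-β accumulates
in the brain, which makes it a candidate blood screen for amyloid
pathology ahead of CSF sampling or amyloid-PET. Using it as a screen
requires a positivity cutoff, and a way to translate the cutoff's
sensitivity and specificity into the quantity a clinician acts on: the
probability of brain amyloidosis after a positive or negative blood test,
at the patient's pretest prevalence. This package implements both halves —
threshold derivation and the posttest calculus — together with the
deterministic cohort rules that define the analysis population.

Throughout, the decision rule is fixed a priori: a ratio **at or below**
the cutoff is plasmatic Aβ+ (ties classify as positive), and the
positivity direction is never auto-detected from the data — on noisy
samples, automatic direction detection can silently flip the test.

## Cohort rules

A cohort is a plain data frame, one row per participant
(see `?cohort`). The derived classifications are deterministic:

* **Amyloid reference status** (`call_amyloid()`): CSF Aβ42 below
  438 pg/mL, or a PET Centiloid above 26, is amyloid positive; a measured
  value on the other side is negative; with no measurement the status is
  unknown. When both modalities are present, CSF decides by default — the
  choice is configurable and disagreements are flagged, since no
  principled precedence exists when the two disagree.
* **Dementia** (`has_dementia()`): MMSE below 24/30.
* **APOE ε4 carriage** (`is_e4_carrier()`): any genotype containing an ε4
  allele (ε2ε4, ε3ε4, ε4ε4).
* **Eligibility** (`is_eligible()`): the amyloid reference measurement
  must fall within `window_days` of the blood draw in either direction —
  default 730 days, a fixed two 365-day years, since calendar "2 years"
  leaves leap handling ambiguous — *except* that a positive measurement
  taken before the blood draw stays valid at any delay: without
  anti-amyloid treatment, an amyloid-positive person remains positive.
  Participants with unknown status are ineligible for the supervised
  analyses.

Missing MMSE or genotype raise errors in these per-participant rules
rather than silently classifying, because downstream subgrouping depends
on them; the bulk annotation path (`annotate_cohort()`) instead propagates
`NA`.

## The mixture threshold

The unsupervised estimator treats the marginal distribution of the ratio
across *all* participants — labeled or not, the deliberate asymmetry
versus the supervised stages — as a two-component Gaussian mixture
$\pi_1\,\varphi(x;\mu_1,\sigma_1) + \pi_2\,\varphi(x;\mu_2,\sigma_2)$
with unequal variances, component 1 being the lower-ratio (amyloid
positive) one. Before fitting, an interquartile-range filter removes
values outside $[q_{0.25} - 1.5\,\mathrm{IQR},\; q_{0.75} +
1.5\,\mathrm{IQR}]$, with fences computed once from the full sample (not
iteratively) and quartiles by linear interpolation between order
statistics (`stats::quantile()` type 7) — the interpolation rule is
pinned because different conventions move the fences.

### EM details

`fit_gmm_em()` maximises the likelihood by EM with:

* **tolerance** `1e-8` (absolute) on the log-likelihood increase,
  iteration cap 2000;
* **variance floor** `1e-12`, so a component cannot collapse onto a
  single observation (the unequal-variance likelihood is unbounded);
* **starting points**: a deterministic grid of two-group partitions, the
  data cut at each quantile 0.2, 0.3, …, 0.8, keeping the converged
  solution with the best log-likelihood; seeded jittered restarts only as
  a fallback when no grid start converges.

The starting-point design deserves its own paragraph. When the two
components overlap as much as plasma Aβ ratios do, the likelihood surface
at a few hundred observations carries several local maxima, and the
highest ones are often *spurious*: a dominant broad component plus a
narrow "shoulder" component hugging one tail. Chasing the global maximum
with many random restarts systematically selects these shoulders, whose
crossing point is far from the population decision boundary. Running
tight EM from a spread of balanced and unbalanced deterministic cuts, and
comparing only converged solutions, keeps the interpretable decomposition
when it is competitive while remaining reproducible — no randomness enters
unless every deterministic start fails.

### The crossing point

`gaussian_intersection()` solves
$\pi_1\varphi(t;\mu_1,\sigma_1) = \pi_2\varphi(t;\mu_2,\sigma_2)$ in
closed form: equating log densities gives a quadratic in $t$ (linear when
$\sigma_1 = \sigma_2$), and the root between the component means is the
cutoff. With mixing weights included (the default) this crossing is
exactly the posterior-0.5 classification boundary of the fitted mixture.
A density plot of the two fitted curves can be read either way —
weight-scaled or unit-scaled — so `weighted = FALSE` computes the
unit-weight crossing instead. With strongly unbalanced weights the
weighted curves may fail to cross between the means; the error then
carries both quadratic roots for inspection, and the pipeline falls back
to the unweighted crossing with a warning.

## The stump threshold

`fit_stump()` is a depth-one decision tree on the single feature:
candidate cutpoints are the midpoints between consecutive distinct sorted
values (the midpoint convention matters when reporting data-dependent
cutoffs), the objective is the size-weighted Gini impurity, the search is
exhaustive, and ties resolve to the smallest cutpoint so the result is
deterministic. The left branch (≤ cutpoint) predicts amyloid positive;
the direction is fixed, not learned. The headline analysis trains on all
labeled data with no cross-validation — the estimand is the threshold
itself, not a generalisation error — but `cv_stump()` provides a k-fold
evaluation as a clearly separated extension.

## ROC, AUC and the Youden cutoff

`roc_curve()` places one point per distinct observed value plus the two
trivial endpoints, computes sensitivity and specificity under the
≤-positive rule, and integrates by trapezoid — which for an empirical ROC
equals the Mann–Whitney probability $P(X^+ < X^-) + \tfrac12 P(X^+ =
X^-)$; the test suite asserts that identity against a brute-force pair
count. `auc_ci()` offers the DeLong interval from placement-value
variances (default, the convention of standard ROC software) and a
seeded stratified percentile bootstrap; both are clipped to [0, 1].

`youden_threshold()` maximises $J = Sn + Sp - 1$ over observed cutoffs
and reports an observed value, not a midpoint. Ties resolve toward the
higher-specificity (smaller) cutoff: in a screening-then-confirmation
chain, false positives cost confirmatory scans, so among equal-$J$
cutoffs the one sending fewer people onward is preferred.

## Likelihood ratios and posttest probabilities

From an operating point, `likelihood_ratios()` computes
$LR^+ = Sn/(1-Sp)$ and $LR^- = (1-Sn)/Sp$ — note $LR^+$ is sensitivity
over one *minus specificity*; a shorthand sometimes seen, "Sn/(1−p)",
is read as exactly this. `posttest()` chains pretest probability → odds
($p/(1-p)$) → posttest odds (multiply by the LR of the observed result) →
probability ($o/(1+o)$). All arithmetic uses exact count fractions;
rounding (half away from zero, one decimal for percentages) happens only
at report time, because chaining pre-rounded intermediate values changes
final digits. One consequence worth knowing: published grids computed
from *truncated* intermediate odds can differ by one final digit from the
exact-fraction chain, and reproducing such a grid exactly requires
feeding the printed odds into the product, which the test suite
demonstrates.

The default pretest prevalences for the posttest grid are 15.8% at age 60
and 32.6% at age 80 — published amyloid prevalences among clinically
normal adults. Between those ages no interpolation rule is endorsed for
*clinical* use (prevalence curves are not linear in general); the
generator's `prevalence_at_age()` interpolates linearly between the
anchors, flat outside, purely to give simulated cohorts a realistic age
gradient.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the structure the analysis
assumes; `paper_like_config()` is the study-shaped default: 277
volunteers, 70 AD patients, 18 non-AD patients; all patients and 73/277
of volunteers carry a CSF or PET reference measurement; measurement
delays place roughly 15% of measured participants outside the two-year
window (mostly measured before the blood draw), exercising the
eligibility filter and its prior-positive exception so the eligible
labeled set lands near 151 participants, ~126 of them without dementia.

Each participant receives a latent amyloid status — from the
age-prevalence curve for volunteers, from fixed group probabilities for
AD (0.87) and non-AD (0.0625) patients, both taken from the labeled
group margins of the study design — and then a ratio drawn from the
matching Gaussian component, truncated at zero by rejection (negligible
at the calibrated parameters). The component defaults,

* Aβ+: mean 0.0450, SD 0.0030,
* Aβ−: mean 0.0495, SD 0.0070,

were calibrated once against four population anchors: the crossing of the
weighted components at the expected mixing proportion sits at 0.0470, the
binormal AUC at 0.723, the maximal Youden $J$ at 0.437, and the operating
point at a 0.0472 cutoff at Sn 0.77 / Sp 0.63 — overlap comparable to the
published discrimination of SIMOA plasma ratios. They are a plausible
stand-in, **not** the study's (unpublished) component estimates.
`analytic_intersection()` returns the population crossing implied by a
configuration, the target that fits on generated cohorts should recover.

CSF and Centiloid values are drawn uniformly on the correct side of their
cutoffs given the latent status (zero label noise by default; a
`label_noise` parameter flips a configurable fraction to emulate
imperfect plasma–CSF/PET concordance). APOE ε4 carriage is conditioned
on latent status (70% among Aβ+, 30% among Aβ−); MMSE is drawn by
dementia status (non-demented 28.4 ± 1.3 clamped to [24, 30]; demented
19 ± 3 clamped to [0, 23]); ages are truncated normals per group matching
the study's demographics.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: assay measurement error beyond the
Gaussian components (no plate effects, no lower-quantification limits),
any direct age trend in the ratio itself, skewed or heavy-tailed
component shapes, longitudinal drift, and the marginal APOE rate of an
unselected volunteer panel (conditioning on status at the labeled-subset
rates overstates the volunteer carrier fraction, since real labeled
subsets are often ε4-enriched by design). Naturally drawn cohorts already
contain ~2% IQR-fence outliers from the wide negative component, matching
the outlier rate such analyses report, so no extreme values are planted
by default; an `n_outliers` knob plants unambiguous extremes for testing
the filter.

## Numerical and degenerate-input behaviour

* All-equal values: IQR fences collapse and nothing is removed; the
  mixture and the stump refuse to fit (no spread, no valid split).
* Fewer than 4 finite values: the IQR filter errors; fewer than 10: the
  EM errors; single-class labels: stump and ROC error, and the pipeline
  skips the supervised stages with a warning while still reporting the
  mixture threshold.
* Specificity 1 yields an infinite $LR^+$ (posttest probability 1);
  specificity 0 leaves $LR^-$ undefined and errors.
* Ties-only data give a degenerate (zero-variance) DeLong statistic and
  error; separable data collapse the interval to [1, 1].
* JSON reports are byte-stable for identical inputs; every stochastic
  step (generator, EM fallback restarts, bootstrap) is seeded.

## Test problem sizes

The suite exercises parameter recovery on mixtures of 10⁴ draws (eight
replicates, agreement within three simulation standard errors),
closed-form crossings against a bisection oracle at 10⁻¹⁰, stump cuts
against an exhaustive Gini scan up to n = 500, AUC against pair counting
up to n ≈ 200, and crossing recovery on fifty study-sized (n = 365)
generated cohorts, comparing the replicate mean against the analytic
crossing. Those sizes keep the full suite around two minutes on one CPU
while leaving the statistical assertions comfortably powered.

## Known limitations

At study-scale sample sizes (a few hundred observations) and the
calibrated overlap, the unequal-variance decomposition is weakly
identified: single-cohort crossing estimates scatter by roughly ±0.002–
0.004 around the population value, occasionally the fitted components do
not cross between their means at all (the pipeline then falls back to the
unweighted crossing), and applying the IQR filter to clean mixture draws
truncates the wide component's tails, biasing the crossing upward by
~+0.002–0.005 on synthetic cohorts. The supervised thresholds are
step-function estimators with sizable sampling variability at n ≈ 150.
The published ordering of the three cutoffs (Youden < stump < mixture)
reproduces on synthetic cohorts as a tendency across seeds, not a law —
the pipeline tests assert it as a frequency. None of this affects the
probability calculus, which is exact given an operating point.
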