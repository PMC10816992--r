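# abratio

Tools for deriving positivity thresholds for the **plasma Aβ42/Aβ40
ratio** — a blood biomarker of brain amyloidosis — and for turning a
threshold's diagnostic performance into **posttest probabilities** of
amyloid pathology at a given pretest prevalence.

Brain amyloid accumulation, the earliest pathological signature of
Alzheimer's disease, is confirmed today by CSF Aβ42 measurement or
amyloid-PET imaging — invasive or expensive procedures. A low plasma
Aβ42/Aβ40 ratio signals amyloid deposition, so a well-chosen cutoff on
this cheap blood measure can serve as a screening step: individuals above
the cutoff are reassured, individuals at or below it are referred for
confirmatory CSF/PET testing. This package implements the statistical
machinery for choosing and evaluating such cutoffs, for analysts working
with cohorts that mix unlabeled screening participants with a subset whose
amyloid status is confirmed by CSF (Aβ42 < 438 pg/mL ⇒ positive) or
amyloid-PET (Centiloid > 26 ⇒ positive).

## Methods at the core

Three estimators of the cutoff *t* (the screening rule is always
*ratio ≤ t ⇒ plasmatic Aβ+*):

* **Gaussian-mixture crossing** (unsupervised; uses *all* participants,
  labeled or not). After an interquartile-range outlier filter
  (exclude values outside `[q₀.₂₅ − 1.5·IQR, q₀.₇₅ + 1.5·IQR]`), a
  two-component unequal-variance Gaussian mixture
  `π₁·φ(x; μ₁, σ₁) + π₂·φ(x; μ₂, σ₂)` is fitted by EM and the cutoff is
  the crossing `π₁·φ(t; μ₁, σ₁) = π₂·φ(t; μ₂, σ₂)` between the two
  component means, solved in closed form (a quadratic in *t*).
* **Decision stump** (supervised; labeled participants). A depth-one tree
  on the single feature, minimising the size-weighted Gini impurity
  `n_L/n·G(L) + n_R/n·G(R)`, `G = 1 − Σ p_c²`, over all midpoints between
  consecutive distinct values.
* **Youden index** (supervised; labeled participants without dementia).
  The observed cutoff maximising `J = Sn + Sp − 1` on the empirical ROC
  curve, reported with the trapezoidal AUC (equal to the Mann–Whitney
  probability) and a DeLong or bootstrap 95% interval.

A chosen cutoff's sensitivity/specificity convert to likelihood ratios
`LR+ = Sn/(1 − Sp)`, `LR− = (1 − Sn)/Sp`, and then
`posttest odds = pretest odds × LR`, `p = odds/(1 + odds)`.

Because participant-level data for studies in this area are typically not
deposited, the package ships a seeded synthetic-cohort generator
(`generate_cohort()`, `paper_like_config()`) that emulates the relevant
structure — a bimodal ratio, group- and age-dependent amyloid prevalence,
APOE ε4 enrichment among the amyloid-positive, MMSE by dementia status,
and randomized blood-to-amyloid measurement delays — so every stage is
testable end to end.

## Worked example

```r
library(abratio)

report <- run_pipeline(config = paper_like_config(), seed = 1173)
#> generated synthetic cohort: 365 participants
#> mixture stage: 365 ratios, 13 outlier(s) removed by the IQR rule
#> eligibility: 157 measured; 7 retained by the prior-positive exception;
#>   10 excluded (negative measurement > 730 days before blood);
#>   2 excluded (measurement > 730 days after blood)
#> labeled analysis set: 145 (of which 124 without dementia)
print(report)
#> Plasma Abeta42/Abeta40 threshold analysis
#>   gmm    threshold: 0.04620
#>   stump  threshold: 0.05081
#>   youden threshold: 0.04862
#>   AUC (non-demented): 0.703 (95% CI 0.604-0.802, delong)
#>   labeled n = 145 (non-demented 124); mixture n = 352
```

The three thresholds are the mixture crossing, the Gini stump cut and the
Youden optimum; the AUC quantifies how well the ratio separates confirmed
amyloid-positive from amyloid-negative participants without dementia.
`render_report(report, "markdown")` lays out the per-threshold confusion
tables and the posttest grid.

The probability calculus works directly from an operating point. At a
cutoff with sensitivity 44/53 and specificity 42/73 among non-demented
adults, and an amyloid prevalence of 15.8% at age 60:

```r
posttest(prevalence = 0.158, sensitivity = 44/53, specificity = 42/73)
#> Pretest prevalence 15.8% (odds 0.188); LR+ 1.95, LR- 0.30
#>   positive test -> 26.8%; negative test -> 5.2%
```

A negative blood test at this threshold drops the probability of brain
amyloidosis from 15.8% to 5.2%; a positive one raises it to 26.8%,
motivating confirmatory CSF/PET testing.

## Analysis workflow

The `analysis/` directory holds the end-to-end narrative as numbered
drivers, each a thin script over the package functions, writing its
outputs under `results/`:

```sh
Rscript analysis/01_simulate.R     # study-shaped synthetic cohort -> cohort.csv
Rscript analysis/02_thresholds.R   # IQR filter, mixture, stump, ROC/Youden
Rscript analysis/03_performance.R  # confusion tables per threshold and subgroup
Rscript analysis/04_posttest.R     # posttest grid at ages 60 / 80
Rscript analysis/05_report.R       # consolidated JSON + markdown report
```

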