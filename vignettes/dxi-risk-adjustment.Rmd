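---
title: "Concurrent risk adjustment on multi-membership diagnostic classifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concurrent risk adjustment on multi-membership diagnostic classifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health plans and regulators set payments and benchmarks from diagnostic
profiles: a *concurrent* risk-adjustment model predicts a person's spending
(or utilization) in a year from the diagnoses coded in that same year. The
predictive ceiling of such a model is set by how much information the
diagnosis *classification* retains. Flat single-membership groupers
(CCSR-style, one category per code) and coarse hierarchical payment groupers
(HCC-style, with dominance rules and partial code coverage) discard much of
the detail in ICD-10-CM. A multi-membership classification instead lets a
single code carry up to four overlapping main-effect items — broad and
narrow clusters coexisting because the right granularity for prediction is
not known in advance — plus cross-cutting modifiers (severity, laterality)
and numeric scaled variables such as BMI bands.

`dxitools` implements that whole stack as a reusable toolkit: the grouper,
the enrollee-year cohort builder, the weighted estimation machinery, the
evaluation battery, and a synthetic claims generator with known ground truth
so every stage can be tested end to end.

## The model

For enrollee-year $i$ the design row contains age–sex cell indicators
$a_i$ (cell-means coding: every row activates exactly one cell, no
intercept), and binary item indicators $x_{ij}$ — item $j$ is 1 iff any of
the year's distinct, source-filtered diagnoses maps to it. The fitted model
is unconstrained weighted least squares,

$$\min_\beta \sum_i w_i \left(y_i - a_i'\gamma - x_i'\beta\right)^2,$$

where $y_i$ is the annualized outcome and $w_i$ the fraction of the year
enrolled (newborns: observed outcome, $w_i = 1$; their spending concentrates
in the birth episode rather than accruing at an annual rate). Under
cell-means coding a negative *prediction* can only arise from the net effect
of diagnostic coefficients, which makes the weighted share of negative
predictions a meaningful diagnostic in its own right.

Annualizing the outcome and weighting by exposure is the standard device for
partial-year enrollees: if costs accrue roughly in proportion to enrolled
time with exposure-proportional variance, weighting by the enrolled fraction
is (approximately) the efficient generalized-least-squares choice, and the
weighted mean of annualized outcomes conserves total money — it equals total
spend divided by total enrolled years.

### Outcome cleaning

Yearly outcome totals pass through a fixed operator order: **sum** claim
lines → **floor** at \$0 (negative totals are billing artifacts) →
**global top-code** at \$3M (data cleaning) → **deflate** to reference-year
dollars → **annualize** (divide by the enrolled fraction; skipped for
newborns) → **analysis top-code** (\$250K for the primary spending outcome,
\$500K for out-of-pocket). The order is a design decision: cleaning recodes
act on observed yearly totals, analysis top-codes act on the annualized
quantity that enters the regression. Both cap operators are monotone and
idempotent, which the tests assert.

### Stepwise selection

`stepwise_fit()` performs forward selection from a forced base (the age–sex
block, never removable): at each step the candidate whose single-column
addition has the smallest p-value enters if it is strictly below `entry_p`
(default $10^{-4}$), ties broken by column name; after each entry,
previously entered columns whose p-value has risen to the stay threshold
(default: equal to `entry_p`, the SAS convention when SLE = SLS) are removed
worst-first. A stall guard stops the procedure if a removal would be
immediately re-entered. All entry statistics come from one triangular solve
per step against the precomputed weighted Gram system, so the selector
scales with the number of candidates, not with $n$.

Significance reporting uses a Bonferroni correction over the full candidate
family (all columns considered, not only those retained — the conservative
reading) capped at a fixed ceiling of $10^{-4}$.

### Evaluation battery

All validation metrics are weight-modified:

* weighted $R^2 = 1 - \sum w(y-\hat y)^2 / \sum w(y-\bar y_w)^2$;
* weighted MAE $= \sum w|y-\hat y| / \sum w$;
* the weighted Cumming prediction measure
  $1 - \sum w|y-\hat y| / \sum w|y-\bar y_w|$, an $L_1$ analogue of $R^2$
  that can go negative when a model does worse than the weighted-mean
  predictor (the null mean is taken from the evaluation sample itself — a
  configurable convention);
* predictive ratios (mean predicted / mean actual) across weighted
  percentiles of *actual* outcome, using interpolation-free type-1 weighted
  quantiles with inclusive lower edges, stated here for bit-reproducibility;
* mean residuals by diagnostic frequency: each (enrollee-year, distinct
  diagnosis) pair contributes the enrollee-year residual, with its
  regression weight, to the half-open frequency bin
  $[10^k, 10^{k+1})$ per million enrollee-years of its code, frequencies
  taken from the designated full (pre-split) sample. The 95% intervals are
  corrected for clustering at the patient level: each person's weighted
  contributions to a bin are aggregated first and the variance of the
  weighted mean is computed across persons (normal approximation). Large
  rare-bin residual means quantify exactly the enrollees a payer could
  profitably avoid under a coarse payment model.

## Numerical choices

The WLS core solves the weighted normal equations through a sequential
Cholesky factorization that adds columns in matrix order and drops any
column whose pivot falls below $10^{-9}$ relative to its diagonal — the
deterministic "first kept wins" rule for collinear columns. Standard errors
and p-values are classical WLS (the cluster machinery is reserved for the
frequency-residual intervals). The solver is verified in the test suite
against an explicit normal-equations oracle ($10^{-8}$ relative) and
against `stats::lm` under equal weights; the selector is verified against
exhaustive best-subset enumeration on an 11-candidate problem.

Root-stem lookup in the grouper is longest-proper-prefix matching with a
minimum length of 3 characters, mirroring the ICD structure in which the
first three characters form the category; fallback never fires when an
exact entry exists. Unmapped codes are counted and reported, not errors:
real data contain codes newer than any mapping. Dominance hierarchies are
applied simultaneously against the input set (so a severity chain collapses
to its apex in one pass and the operation is idempotent), and hierarchy
content is supplied as data, never hard-coded.

## The synthetic generator

`simulate_claims()` produces a full study with known truth. What it
emulates, and the defaults (all in `sim_config()`):

* **Population**: `n_persons` (default 20,000) followed over `n_years`
  (default 3 calendar years), ages 0–64, 70% full-year enrollment and the
  rest uniform over 1–11 months, 0.8% of persons entering as newborns
  (weight-1 birth-episode records).
* **Code system**: 500 ICD-shaped codes with per-code population
  frequencies log-uniform between 1 and $10^5$ per million enrollee-years,
  so every power-of-ten frequency bin is populated. A 5% share of codes is
  entered at its 3-character root and emitted partly as longer child codes,
  exercising root-stem fallback; 6% are V/Z-style codes carrying only
  modifiers; eight Z68-style codes carry BMI scale bands.
* **Mappings**: narrow main items pool codes of neighboring frequency (as a
  clinical grouper pools similar conditions); 35% of codes additionally get
  a broad parent item and possibly cross-cutting axis items (up to the cap
  of 4 mains per code). The flat comparator assigns every code exactly one
  of 40 categories *at random*, mixing frequencies — which is what hides
  rare-code costs inside category means. The hierarchical comparator covers
  25% of codes with 18 items plus a three-step severity chain.
* **Spending**: annualized spend is exactly linear in age–sex cell bases,
  the distinct fine-system main items (true effects drawn lognormal,
  meanlog $\log 800$, sdlog 1, inflated for rare items via `rare_boost`
  because rare conditions are disproportionately expensive), and a newborn
  effect (\$6,000) — plus a positive lognormal shock (scale \$1,500) and,
  with probability 0.001, an extreme episode near \$400K that exercises the
  top-codes. The observed raw total multiplies everything by the enrolled
  fraction (non-newborns) and is expressed in nominal dollars against a
  supplied deflator series, then spread across the year's claim lines; 0.3%
  of person-years receive a negative billing reversal to exercise the \$0
  floor, and 5% of diagnoses are duplicated onto disallowed claim lines to
  exercise the professional-type filter without losing the diagnosis.

**Why an additive, exposure-scaled shock.** The recorded ground-truth
coefficients are the *exact* conditional means: cell base plus the expected
shock plus the expected extreme contribution. With the shock entering
additively and scaled by the enrolled fraction, the annualized outcome has
(approximately) constant conditional variance, so classical WLS standard
errors are approximately valid and the generator's parameter-recovery
property — at least 95% of true coefficients inside ±3 reported standard
errors — tests the estimator rather than a variance misspecification. A
multiplicative noise family (conditional variance proportional to the
squared mean) would invalidate classical standard errors for high-cost
cells and turn that check into a test of the wrong formula. The two
deliberate distortions that remain — flooring the 0.3% reversal rows at
\$0, and weighting by exposure when the exact GLS weight differs slightly —
perturb conditional means by well under one reported standard error at the
$10^5$-row scale the recovery check uses.

What the generator does **not** emulate: real ICD semantics or clinical
plausibility of the mappings, capitation or adjudication behavior, coding
intensity differences across plans, secular trends, or the real spending
distribution's exact moments. Passing tests therefore demonstrate that the
machinery is correct under the assumed structure, not that any particular
real population satisfies that structure.

## Study sizes used by the checks

The acceptance battery runs at deliberately desk-sized scales: the tiered
model comparison and coefficient-recovery checks use one simulated study of
about 100,000 enrollee-years (34,000 persons over three years; 10%
person-level validation split), and the rare-diagnosis residual check uses
about 330,000 enrollee-years (110,000 persons) with `rare_boost = 6`, the
configuration in which rare-code effects (~\$9K at the rarest items) are
genuinely hidden from the coarse mapping — the premise of that check. At
these scales the rarest populated frequency bins hold on the order of a
hundred (enrollee-year, code) pairs, so the residual profile for those bins
is evaluated on the full simulated sample rather than the 10% validation
slice, which would hold only a handful.

## Open design decisions, resolved

* **Validation split by person, not enrollee-year**, so that within-person
  correlation across years never leaks development information into
  validation.
* **Age bands**: infants (0), 1–4, then 5-year bands to 60–64, crossed with
  sex (28 cells); the exact published 29-cell layout of regulatory models is
  not public, so the banding is configurable rather than guessed.
* **Scale conflicts** within a year resolve to the maximum observed value
  (severity-oriented), with a companion observed-indicator so that absence
  (0) is distinguishable from a low value.
* **Root-stem fallback applies to the whole assignment** (mains, modifiers
  and scales of the matched root), not to partial item sets.
* **Zero-prevalence column pruning** happens on the development sample
  only; validation designs are conformed to the development column set,
  with absent columns as structural zeros.
* **Modifier and scale items are excluded from the default model
  specification** (`include_modifiers`/`include_scales` opt in): the
  headline comparison isolates the value of the main-effect classification.
* **Frequency-bin weights** are the regression weights (the "enrollee
  weighting" convention is ambiguous in general; using the same weights as
  the fit keeps the residual decomposition consistent with the estimator).

## Limitations

Prospective modeling (predicting next year's outcomes), prescription-drug
adjusters, constrained or machine-learned fitters, and payment-policy
simulation are out of scope. The shipped mappings are toys and synthetic
constructions; the package ships no clinical content. Classical standard
errors are reported for selection and flags; only the frequency-residual
intervals are cluster-corrected. Everything reported by the evaluation
battery here is computed by the package's own tests and acceptance script
on synthetic data — no real-data magnitudes are claimed.
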