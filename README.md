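# dxitools

Concurrent claims-based risk adjustment on multi-membership diagnostic
classifications, for health-economics and health-services researchers who
build or evaluate payment and benchmarking models from insurance claims.

Flat diagnosis groupers (one category per code, CCSR-style) and coarse
hierarchical payment groupers (HCC-style) discard much of the detail in
ICD-10-CM. `dxitools` implements the alternative end to end: a grouper in
which one diagnosis code can carry up to four overlapping main-effect items
(broad and narrow clusters side by side) plus cross-cutting modifiers and
numeric scaled variables such as BMI bands, together with everything needed
to turn raw claims into fitted and evaluated concurrent models.

For enrollee-year *i* with age–sex cell indicators *aᵢ* (cell-means coding,
no intercept) and item indicators *xᵢ*, the package fits unconstrained
weighted least squares

    min_β Σᵢ wᵢ (yᵢ − aᵢ'γ − xᵢ'β)²

where *yᵢ* is the annualized outcome (yearly total → floor \$0 → global
top-code \$3M → deflate → divide by the enrolled fraction → analysis
top-code) and *wᵢ* is the fraction of the year enrolled; newborns keep
their observed outcome with weight 1. Forward-stepwise selection with a
p-value entry criterion (default P < 10⁻⁴, SAS-style entry/stay), Bonferroni
significance flags, and a weight-modified evaluation battery — validated
weighted R², weighted MAE, the weighted Cumming prediction measure
1 − Σw|y−ŷ| / Σw|y−ȳ_w|, predictive ratios by spending percentile, and mean
residuals binned by diagnostic frequency (powers of ten per million
enrollee-years) with patient-clustered 95% intervals — complete the stack.
A seeded synthetic-claims generator with known ground truth makes the whole
pipeline testable.

## Worked example

```r
library(dxitools)

# simulate a small synthetic study: 8,000 persons over 2016-2018
sim <- simulate_claims(sim_config(seed = 42, n_persons = 8000))

# filter diagnoses to acceptable sources, build weighted enrollee-years
dx  <- filter_diagnoses(sim$claims, sim$filter_rules)
coh <- build_enrollee_years(sim$spans, sim$claims, dx,
                            deflators = sim$config$deflators)
coh
#> <dxi_cohort> 23953 enrollee-years (8000 persons), 92643 distinct diagnosis
#> pairs, outcomes: total, total_topcoded, plan, plan_topcoded, oop, ...

parts <- split_sample(coh, validation_share = 0.10, seed = 42)

# fit the flat comparator and the rich multi-membership model
fit_tier <- function(systems, id) {
  spec <- model_spec("total_topcoded", c("age_sex", systems))
  dev  <- build_design(parts$development, sim$mappings, spec)
  fit  <- wls_fit(dev$X, dev$y, dev$w, model_id = id)
  val  <- build_design(parts$validation, sim$mappings, spec,
                       columns = colnames(dev$X))
  evaluate_model(fit, val)
}
reports <- list(fit_tier("ccsr_like", "ccsr"),
                fit_tier(c("ccsr_like", "dxi"), "dxi"))
compare_models(reports)
#>     model     n n_columns weighted_r2 weighted_mae weighted_cpm negative_share
#> 1:   ccsr  2373        68   0.3499106     7807.389    0.2939095              0
#> 2:    dxi  2373       205   0.7722301     2195.900    0.8014055              0
```

Reading the output: both models are scored on the same 2,373 validation
enrollee-years. Layering the multi-membership items on top of the flat
categories raises validated weighted R² from 0.35 to 0.77 and cuts the
weighted mean absolute error from \$7,807 to \$2,196 per annualized
enrollee-year — on *this synthetic draw*, where the generator's true
spending model lives exactly on the fine items. The `negative_share`
column is the weighted fraction of validation rows assigned negative
spending; under cell-means coding such predictions can only come from the
net effect of diagnostic coefficients.

The same flow is available from a shell via the thin CLI:

```sh
Rscript inst/cli/dxi_pipeline.R all --config my_config.json --seed 7
```

which writes mapping TSVs, cohort CSVs, fitted-model JSONs, percentile
tables, a model-comparison CSV and a run manifest under the configured
output directory.

## Package layout

| Area | Functions |
| --- | --- |
| Grouper | `read_mapping`, `write_mapping`, `assign_items`, `assignment_table`, `apply_hierarchies`, `summarize_by_chapter` |
| Cohort | `filter_diagnoses`, `outcome_spec`, `build_enrollee_years`, `split_sample` |
| Design | `model_spec`, `age_sex_cells`, `build_design`, `write_design` |
| Estimation | `wls_fit`, `stepwise_fit`, `significance_flags`, `predict`, `write_fit`/`read_fit` |
| Evaluation | `weighted_r2`, `weighted_mae`, `weighted_cpm`, `predictive_ratios`, `code_frequencies`, `residuals_by_frequency`, `evaluate_model`, `compare_models` |
| Synthesis | `sim_config`, `gen_mapping`, `gen_population_claims`, `gen_spending`, `simulate_claims` |
| Orchestration | `read_pipeline_config`, `run_pipeline`, `inst/cli/dxi_pipeline.R` |

The methods vignette (`vignettes/dxi-risk-adjustment.Rmd`) documents the
model, the cleaning order, the numerical choices, the synthetic generator's
assumptions and their limits, and the resolved design decisions.
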