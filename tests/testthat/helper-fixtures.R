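library(data.table)

extdata <- function(name) system.file("extdata", name, package = "dxitools")

toy_mapping <- function() {
  read_mapping(extdata("toy_mapping.tsv"), "dxi",
               scale_ranges = data.frame(item_id = "BMI", min = 18.5, max = 70))
}

toy_hcc_mapping <- function() {
  read_mapping(extdata("toy_hierarchy_mapping.tsv"), "hcc_like",
               hierarchy_path = extdata("toy_hierarchy.tsv"))
}

toy_filter_rules <- function() read_filter_rules(extdata("toy_filter_rules.tsv"))

# --- hand-built cohort inputs ------------------------------------------------

make_spans <- function(person_id, year = 2018L, months = 12L, age = 30L,
                       sex = "M", newborn = FALSE) {
  data.table(person_id = person_id, year = year, months_enrolled = months,
             age = age, sex = sex, newborn = newborn)
}

# one claim line per row of the arguments, with benign defaults
make_claims <- function(person_id, year = 2018L, paid_total = 0,
                        diagnosis_codes = "", setting = "professional",
                        professional_type = "md", service_type = "other",
                        plan_share = 0.8, admissions = 0L, ip_days = 0L,
                        ed_visits = 0L) {
  data.table(person_id = person_id, year = year, setting = setting,
             professional_type = professional_type, service_type = service_type,
             diagnosis_codes = diagnosis_codes, paid_total = paid_total,
             paid_plan = paid_total * plan_share,
             paid_oop = paid_total * (1 - plan_share),
             admissions = admissions, ip_days = ip_days, ed_visits = ed_visits)
}

flat_deflators <- c("2016" = 1, "2017" = 1, "2018" = 1)

# --- independent oracles -----------------------------------------------------

# explicit normal-equations WLS (dense, no pivoting): the brute-force oracle
wls_oracle <- function(X, y, w) {
  X <- as.matrix(X)
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)[, 1L]
}

# scalar-loop weighted metrics
r2_oracle <- function(y, yhat, w) {
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2)
}
mae_oracle <- function(y, yhat, w) sum(w * abs(y - yhat)) / sum(w)
cpm_oracle <- function(y, yhat, w) {
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * abs(y - yhat)) / sum(w * abs(y - ybar))
}

# person-level cohort subset without reaching into package internals
subset_cohort_for_test <- function(cohort, persons) {
  structure(list(years = cohort$years[person_id %in% persons],
                 diagnoses = cohort$diagnoses[person_id %in% persons],
                 specs = cohort$specs, report = cohort$report),
            class = "dxi_cohort")
}

# cached default-scale synthetic study shared across test files (built once
# per test run; ~100k enrollee-years)
study_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(study_cache$sim)) {
    sim <- simulate_claims(sim_config(seed = 424242L, n_persons = 34000L))
    dx <- filter_diagnoses(sim$claims, sim$filter_rules)
    cohort <- build_enrollee_years(sim$spans, sim$claims, dx,
                                   deflators = sim$config$deflators)
    parts <- split_sample(cohort, 0.10, seed = 424242L)
    study_cache$sim <- sim
    study_cache$cohort <- cohort
    study_cache$parts <- parts
  }
  list(sim = study_cache$sim, cohort = study_cache$cohort,
       parts = study_cache$parts)
}
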