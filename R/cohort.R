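# Enrollee-year cohort construction.
#
# Turns enrollment spans and claim lines into weighted enrollee-year records:
# diagnoses filtered to acceptable care sources, outcomes summed per
# person-year and then cleaned (floor, global top-code), deflated to
# reference-year dollars, annualized to a 12-month rate, and finally
# top-coded at the analysis cap. Non-newborn regression weights equal the
# fraction of the year enrolled; newborns keep their observed outcome and a
# weight of 1 (their spending concentrates in the birth episode rather than
# accruing at an annual rate).

#' Define an analysis outcome
#'
#' An outcome spec names a claim-line field to aggregate per enrollee-year
#' and the cleaning applied to the yearly total. The fixed order of
#' operations is: sum over the year's lines, floor at `floor`, top-code at
#' `global_cap` (data cleaning), multiply by the year's deflator (when
#' `deflate`), annualize (divide by the enrolled fraction; skipped for
#' newborns), then top-code the annualized value at `analysis_cap`.
#'
#' @param name outcome name (column name in the enrollee-year table).
#' @param component what to aggregate: `"total"`, `"plan"` or `"oop"` sum the
#'   corresponding paid field; `"admissions"`, `"ip_days"`, `"ed_visits"` sum
#'   those count fields; any other value is treated as a service type and
#'   sums plan-paid amounts on lines of that `service_type`.
#' @param floor lower recode applied to the yearly total (default $0:
#'   negative totals are billing artifacts).
#' @param global_cap data-cleaning top-code applied to the yearly total.
#' @param analysis_cap optional top-code applied to the annualized value;
#'   must not exceed `global_cap`.
#' @param deflate logical; multiply by the year's price deflator (sensible
#'   for dollars, not for counts).
#' @return A list of class `outcome_spec`.
#' @export
outcome_spec <- function(name, component = "total", floor = 0, global_cap = 3e6,
                         analysis_cap = NULL, deflate = TRUE) {
  if (!is.null(analysis_cap) && analysis_cap > global_cap) {
    stop("analysis_cap must not exceed global_cap for outcome ", name)
  }
  structure(list(name = name, component = component, floor = floor,
                 global_cap = global_cap, analysis_cap = analysis_cap,
                 deflate = deflate),
            class = "outcome_spec")
}

#' Default outcome battery
#'
#' Five spending outcomes (total and plan-paid, each with and without a
#' $250,000 analysis top-code, and out-of-pocket top-coded at $500,000; all
#' floored at $0 and globally capped at $3 million during cleaning), three
#' utilization counts, and plan-paid spending for six service types.
#'
#' @return Named list of [outcome_spec()] objects.
#' @export
default_outcome_specs <- function() {
  sp <- list(
    outcome_spec("total",          "total"),
    outcome_spec("total_topcoded", "total", analysis_cap = 250000),
    outcome_spec("plan",           "plan"),
    outcome_spec("plan_topcoded",  "plan", analysis_cap = 250000),
    outcome_spec("oop",            "oop", analysis_cap = 500000),
    outcome_spec("admissions",     "admissions", global_cap = Inf, deflate = FALSE),
    outcome_spec("ip_days",        "ip_days", global_cap = Inf, deflate = FALSE),
    outcome_spec("ed_visits",      "ed_visits", global_cap = Inf, deflate = FALSE),
    outcome_spec("ip_facility_rx", "ip_facility_rx"),
    outcome_spec("op_facility_rx", "op_facility_rx"),
    outcome_spec("retail_rx",      "retail_rx"),
    outcome_spec("lab",            "lab"),
    outcome_spec("imaging",        "imaging"),
    outcome_spec("preventive",     "preventive")
  )
  setNames(sp, vapply(sp, `[[`, "", "name"))
}

# floor-then-cap cleaning operator; monotone and idempotent
clean_outcome <- function(x, floor, cap) pmin(pmax(x, floor), cap)

#' Read diagnosis filtering rules
#'
#' @param path TSV with header columns `setting`, `professional_type`; a
#'   `"*"` professional type matches any.
#' @return data.table of allowed (setting, professional_type) pairs.
#' @export
read_filter_rules <- function(path) {
  rules <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("setting", "professional_type") %in% names(rules))) {
    stop("filter rules must have columns: setting, professional_type")
  }
  rules
}

KNOWN_SETTINGS <- c("inpatient", "outpatient", "professional", "other")

#' Filter claim-line diagnoses to acceptable care sources
#'
#' Keeps only diagnoses coded on claim lines whose (setting, professional
#' type) pair appears in the rules table, mirroring regulatory filters that
#' restrict risk-adjustment diagnoses to acceptable health care professional
#' types. Lines with an unrecognized setting are routed to `"other"` before
#' matching, dropped when that is disallowed, and counted.
#'
#' @param claims claim-line data.table; needs `person_id`, `year`, `setting`,
#'   `professional_type` and `diagnosis_codes` (semicolon-separated, possibly
#'   empty).
#' @param rules data.table of allowed pairs, see [read_filter_rules()];
#'   `NULL` allows everything.
#' @return data.table of surviving diagnoses (`person_id`, `year`, `code`),
#'   one row per (line, diagnosis); attribute `report` counts removals by
#'   (setting, professional_type).
#' @export
filter_diagnoses <- function(claims, rules = NULL) {
  claims <- as.data.table(claims)
  has_dx <- !is.na(claims$diagnosis_codes) & claims$diagnosis_codes != ""
  dx <- claims[has_dx, .(person_id, year, setting, professional_type,
                         code = diagnosis_codes)]
  if (nrow(dx)) {
    dx <- dx[, .(code = unlist(strsplit(code, ";", fixed = TRUE))),
             by = .(person_id, year, setting, professional_type)]
  }
  dx[!setting %in% KNOWN_SETTINGS, setting := "other"]
  n_total <- nrow(dx)
  if (is.null(rules)) {
    keep <- rep(TRUE, n_total)
  } else {
    rules <- as.data.table(rules)
    exact <- paste(dx$setting, dx$professional_type)
    star <- paste(dx$setting, "*")
    allowed_pairs <- paste(rules$setting, rules$professional_type)
    keep <- exact %in% allowed_pairs | star %in% allowed_pairs
  }
  removed <- dx[!keep, .N, by = .(setting, professional_type)]
  out <- dx[keep, .(person_id, year, code = normalize_icd(code))]
  setattr(out, "report", list(n_diagnoses = n_total, n_kept = nrow(out),
                              n_removed = n_total - nrow(out),
                              removed_by_source = removed))
  out
}

#' Build weighted enrollee-year records
#'
#' @param spans enrollment table: one row per person-year with `person_id`,
#'   `year`, `months_enrolled` (1-12), `age` (0-64, at year start), `sex`
#'   (`"F"`/`"M"`) and `newborn` (logical).
#' @param claims claim-line table (see [filter_diagnoses()] for the diagnosis
#'   fields); paid fields `paid_total`, `paid_plan`, `paid_oop`, count fields
#'   `admissions`, `ip_days`, `ed_visits`, and `service_type` are used as
#'   named by the outcome specs. Claims without a matching enrollment span
#'   are dropped and counted.
#' @param diagnoses filtered diagnosis stream from [filter_diagnoses()]; pass
#'   `NULL` to derive one from `claims` with allow-all rules.
#' @param specs list of [outcome_spec()]s (default [default_outcome_specs()]).
#' @param deflators named numeric vector mapping year to a price deflator
#'   multiplier (reference year = 1); required for every observed year when
#'   any spec deflates.
#' @return A `dxi_cohort`: list with `years` (one row per person-year:
#'   enrollment fields, `fraction`, `weight`, one column per outcome),
#'   `diagnoses` (distinct `person_id`, `year`, `code`), `specs`, and a
#'   `report` of exclusions.
#' @export
build_enrollee_years <- function(spans, claims, diagnoses = NULL,
                                 specs = default_outcome_specs(),
                                 deflators = NULL) {
  if (!length(specs)) stop("at least one outcome spec is required")
  spans <- as.data.table(spans)
  claims <- as.data.table(claims)
  req <- c("person_id", "year", "months_enrolled", "age", "sex", "newborn")
  if (length(miss <- setdiff(req, names(spans)))) {
    stop("spans lack column(s): ", paste(miss, collapse = ", "))
  }
  if (any(spans$age < 0 | spans$age > 64)) {
    stop("age must lie in [0, 64] after eligibility filtering")
  }

  excluded <- spans[months_enrolled < 1L]
  spans <- spans[months_enrolled >= 1L]
  years_obs <- sort(unique(spans$year))
  needs_deflate <- any(vapply(specs, `[[`, TRUE, "deflate"))
  if (needs_deflate) {
    if (is.null(deflators)) stop("deflators are required (one factor per observed year)")
    missing_years <- setdiff(as.character(years_obs), names(deflators))
    if (length(missing_years)) {
      stop("missing deflator for year(s): ", paste(missing_years, collapse = ", "))
    }
  }

  ey <- copy(spans)
  ey[, fraction := months_enrolled / 12]
  ey[, weight := fifelse(newborn, 1, fraction)]
  setkey(ey, person_id, year)

  # claims on person-years without an enrollment span are unusable
  in_span <- paste(claims$person_id, claims$year) %in% paste(ey$person_id, ey$year)
  n_orphan <- sum(!in_span)
  claims <- claims[in_span]

  for (spec in specs) {
    comp <- spec$component
    if (comp %in% c("total", "plan", "oop")) {
      col <- paste0("paid_", comp)
      raw <- claims[, .(v = sum(get(col))), by = .(person_id, year)]
    } else if (comp %in% c("admissions", "ip_days", "ed_visits")) {
      raw <- claims[, .(v = sum(get(comp))), by = .(person_id, year)]
    } else {
      raw <- claims[service_type == comp, .(v = sum(paid_plan)), by = .(person_id, year)]
    }
    ey[, (spec$name) := 0]
    ey[raw, (spec$name) := i.v, on = c("person_id", "year")]
    v <- clean_outcome(ey[[spec$name]], spec$floor, spec$global_cap)
    if (spec$deflate) v <- v * unname(deflators[as.character(ey$year)])
    v <- fifelse(ey$newborn, v, v / ey$fraction)
    if (!is.null(spec$analysis_cap)) v <- pmin(v, spec$analysis_cap)
    ey[, (spec$name) := v]
  }

  if (is.null(diagnoses)) diagnoses <- filter_diagnoses(claims, rules = NULL)
  dx <- unique(as.data.table(diagnoses)[, .(person_id, year, code)])
  dx <- dx[ey[, .(person_id, year)], on = c("person_id", "year"), nomatch = NULL]
  setkey(dx, person_id, year, code)

  structure(list(
    years = ey[], diagnoses = dx, specs = specs,
    report = list(n_person_years = nrow(ey),
                  n_excluded_zero_months = nrow(excluded),
                  n_orphan_claims = n_orphan,
                  years = years_obs)
  ), class = "dxi_cohort")
}

#' @export
print.dxi_cohort <- function(x, ...) {
  cat(sprintf("<dxi_cohort> %d enrollee-years (%d persons), %d distinct diagnosis pairs, outcomes: %s\n",
              nrow(x$years), uniqueN(x$years$person_id), nrow(x$diagnoses),
              paste(names(x$specs), collapse = ", ")))
  invisible(x)
}

# subset a cohort to a set of person ids, keeping all their years
subset_cohort <- function(cohort, persons) {
  structure(list(
    years = cohort$years[person_id %in% persons],
    diagnoses = cohort$diagnoses[person_id %in% persons],
    specs = cohort$specs,
    report = cohort$report
  ), class = "dxi_cohort")
}

#' Split a cohort into development and validation samples
#'
#' The split is by person: every enrollee-year of a person lands on the same
#' side, so validation metrics are not contaminated by within-person
#' correlation across years. Each person is assigned to validation with
#' probability `validation_share`, deterministically under `seed`.
#'
#' @param cohort a `dxi_cohort`.
#' @param validation_share share of persons reserved for validation,
#'   strictly between 0 and 1 (default 0.10).
#' @param seed integer seed controlling the assignment.
#' @return List with `dxi_cohort` elements `development` and `validation`.
#' @export
split_sample <- function(cohort, validation_share = 0.10, seed = 1L) {
  stopifnot(inherits(cohort, "dxi_cohort"))
  if (!(validation_share > 0 && validation_share < 1)) {
    stop("validation_share must lie strictly between 0 and 1")
  }
  persons <- sort(unique(cohort$years$person_id))
  pick <- with_seed(child_seed(seed, 101L),
                    runif(length(persons)) < validation_share)
  val <- persons[pick]
  list(development = subset_cohort(cohort, setdiff(persons, val)),
       validation = subset_cohort(cohort, val))
}
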