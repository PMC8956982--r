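test_that("diagnosis filtering keeps only acceptable care sources and accounts for removals", {
  # 10 diagnoses, 3 on disallowed lines (professional/chiro, other/*)
  claims <- make_claims(
    person_id = sprintf("P%d", 1:8),
    diagnosis_codes = c("A010;B012", "C430", "D120", "E110;E119", "F320",
                        "G001", "H250", "I214"),
    setting = c("inpatient", "outpatient", "professional", "professional",
                "professional", "professional", "other", "weird_setting"),
    professional_type = c("*", "*", "md", "np", "chiro", "md", "md", "md"))
  rules <- toy_filter_rules()
  out <- filter_diagnoses(claims, rules)
  rep <- attr(out, "report")
  expect_equal(rep$n_diagnoses, 10L)
  expect_equal(nrow(out), 7L)
  expect_equal(rep$n_removed, 3L)
  expect_equal(rep$n_kept + rep$n_removed, rep$n_diagnoses)
  # the unknown setting was routed to "other" before matching
  expect_true("other" %in% rep$removed_by_source$setting)
  expect_setequal(out$code, c("A010", "B012", "C430", "D120", "E110", "E119", "G001"))

  # allow-all rules are the identity
  all_out <- filter_diagnoses(claims, NULL)
  expect_equal(nrow(all_out), 10L)
})

test_that("annualization, cleaning order, weighting and newborn handling follow the stated rules", {
  spans <- make_spans(c("A", "B", "C", "D"), months = c(6L, 12L, 12L, 3L),
                      age = c(30L, 40L, 50L, 0L),
                      newborn = c(FALSE, FALSE, FALSE, TRUE))
  claims <- make_claims(c("A", "B", "C", "D"),
                        paid_total = c(500, -50, 3.5e6, 1200))
  specs <- list(outcome_spec("total", "total", analysis_cap = 250000),
                outcome_spec("raw_total", "total"))
  coh <- build_enrollee_years(spans, claims, specs = specs,
                              deflators = flat_deflators)
  ey <- coh$years[order(person_id)]
  # 6 months enrolled, $500 raw -> $1000 annualized, weight 0.5
  expect_equal(ey[person_id == "A", total], 1000)
  expect_equal(ey[person_id == "A", weight], 0.5)
  # negative totals floored to $0 before annualization
  expect_equal(ey[person_id == "B", total], 0)
  # $3.5M -> global cap $3M -> annualized -> analysis cap $250K
  expect_equal(ey[person_id == "C", total], 250000)
  expect_equal(ey[person_id == "C", raw_total], 3e6)
  # newborns are not annualized and get weight 1
  expect_equal(ey[person_id == "D", total], 1200)
  expect_equal(ey[person_id == "D", weight], 1)
})

test_that("deflation converts to reference-year dollars per observed year", {
  spans <- make_spans(c("A", "A"), year = c(2016L, 2018L))
  claims <- make_claims(c("A", "A"), year = c(2016L, 2018L), paid_total = 100)
  coh <- build_enrollee_years(spans, claims,
                              specs = list(outcome_spec("total", "total")),
                              deflators = c("2016" = 1.05, "2018" = 1))
  expect_equal(coh$years[year == 2016, total], 105)
  expect_equal(coh$years[year == 2018, total], 100)
  expect_error(build_enrollee_years(spans, claims,
                                    specs = list(outcome_spec("total", "total")),
                                    deflators = c("2018" = 1)),
               "missing deflator.*2016")
})

test_that("annualization conserves money and diagnosis sets deduplicate", {
  set.seed(3)
  n <- 200
  spans <- make_spans(sprintf("P%03d", 1:n), months = sample(1:12, n, TRUE))
  raw <- round(runif(n, 0, 30000), 2)
  claims <- make_claims(spans$person_id, paid_total = raw,
                        diagnosis_codes = "A010;A010;B012")
  coh <- build_enrollee_years(spans, claims,
                              specs = list(outcome_spec("total", "total")),
                              deflators = flat_deflators)
  ey <- coh$years
  # weighted mean of annualized outcomes = total spend / total enrolled years
  expect_equal(wmean <- sum(ey$weight * ey$total) / sum(ey$weight),
               sum(raw) / sum(spans$months_enrolled / 12), tolerance = 1e-12)
  # duplicate codings contribute a single set element
  expect_equal(nrow(coh$diagnoses), 2L * n)

  # floor/cap cleaning is monotone and idempotent
  x <- c(-100, 0, 5, 2.5e5, 9e6)
  once <- pmin(pmax(x, 0), 250000)
  expect_identical(pmin(pmax(once, 0), 250000), once)
  expect_true(all(diff(once[order(x)]) >= 0))
})

test_that("person-years without enrolled months are excluded and accounted", {
  spans <- make_spans(c("A", "B"), months = c(0L, 12L))
  claims <- make_claims("B", paid_total = 10)
  coh <- build_enrollee_years(spans, claims,
                              specs = list(outcome_spec("total", "total")),
                              deflators = flat_deflators)
  expect_equal(nrow(coh$years), 1L)
  expect_equal(coh$report$n_excluded_zero_months, 1L)
  expect_equal(coh$report$n_person_years + coh$report$n_excluded_zero_months,
               nrow(spans))
})

test_that("the validation split is by person, seeded, and binomially sized", {
  n <- 10000L
  spans <- make_spans(rep(sprintf("P%05d", 1:n), each = 2L),
                      year = rep(c(2017L, 2018L), n))
  claims <- make_claims("P00001", year = 2017L, paid_total = 1)
  coh <- build_enrollee_years(spans, claims,
                              specs = list(outcome_spec("total", "total")),
                              deflators = flat_deflators)
  expect_error(split_sample(coh, 0), "strictly between")
  expect_error(split_sample(coh, 1), "strictly between")

  s1 <- split_sample(coh, 0.10, seed = 99)
  s2 <- split_sample(coh, 0.10, seed = 99)
  expect_identical(s1$validation$years$person_id, s2$validation$years$person_id)

  # all years of a person fall on the same side
  expect_length(intersect(s1$development$years$person_id,
                          s1$validation$years$person_id), 0)
  expect_equal(nrow(s1$validation$years) %% 2L, 0L)

  # realized person count within the 99.99% binomial interval for share 0.10
  n_val <- uniqueN(s1$validation$years$person_id)
  expect_gte(n_val, 900L)
  expect_lte(n_val, 1100L)
})
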