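test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77, n_persons = 500L)
  m1 <- gen_mapping(cfg)
  m2 <- gen_mapping(cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(m1$mappings$dxi, f1)
  write_mapping(m2$mappings$dxi, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical files
  expect_identical(m1$true_beta, m2$true_beta)

  s1 <- simulate_claims(cfg)
  s2 <- simulate_claims(cfg)
  expect_identical(s1$spans, s2$spans)
  expect_identical(s1$claims, s2$claims)

  # a different seed changes the draw
  s3 <- simulate_claims(sim_config(seed = 78, n_persons = 500L))
  expect_false(identical(s1$claims$paid_total, s3$claims$paid_total))
})

test_that("overlap bounds on main-item multiplicity hold at the extremes", {
  n_main_per_code <- function(mp) {
    e <- mp$mappings$dxi$entries[kind == "main"]
    # restrict to codes that carry any main item (V/Z codes legally have none)
    e[, .N, by = code]$N
  }
  m0 <- gen_mapping(sim_config(seed = 5, overlap_rate = 0))
  expect_true(all(n_main_per_code(m0) == 1L))
  m1 <- gen_mapping(sim_config(seed = 5, overlap_rate = 1))
  counts <- n_main_per_code(m1)
  expect_true(all(counts >= 2L & counts <= 4L))
})

test_that("generated mappings carry the structures the grouper supports", {
  mp <- gen_mapping(sim_config(seed = 12))
  dxi <- mp$mappings$dxi
  # modifier-only V/Z codes exist
  vz <- dxi$entries[substr(code, 1, 1) %in% c("V", "Z") & !grepl("^Z68", code)]
  expect_gt(nrow(vz), 0)
  expect_true(all(vz$kind == "modifier"))
  # a scale item with declared range
  expect_equal(dxi$scale_ranges$item_id, "BMI")
  # comparator systems cover the same code universe (flat) or a subset (hcc)
  ccsr <- mp$mappings$ccsr_like
  expect_equal(sort(unique(ccsr$entries$code)), sort(unique(mp$codes$code)))
  expect_true(all(ccsr$entries[, .N, by = code]$N == 1L))
  hcc <- mp$mappings$hcc_like
  expect_lt(uniqueN(hcc$entries$code), uniqueN(ccsr$entries$code))
  expect_equal(nrow(hcc$hierarchy), 2L)
  # root-stem codes exist and emitted variants resolve to them
  expect_gt(sum(mp$codes$emit_variant), 0)
})

test_that("newborn_rate 0 yields no newborn flags and n_persons 0 empty tables", {
  s <- gen_population_claims(sim_config(seed = 3, n_persons = 300L, newborn_rate = 0),
                             gen_mapping(sim_config(seed = 3, n_persons = 300L, newborn_rate = 0)))
  expect_false(any(s$spans$newborn))
  s0 <- gen_population_claims(sim_config(seed = 3, n_persons = 0L),
                              gen_mapping(sim_config(seed = 3, n_persons = 0L)))
  expect_equal(nrow(s0$spans), 0L)
})

test_that("with noise, extremes and reversals off, spending equals the linear model exactly", {
  cfg <- sim_config(seed = 19, n_persons = 800L,
                    noise = list(scale = 0, sdlog = 0),
                    extreme_rate = 0, negative_adjustment_rate = 0)
  sim <- simulate_claims(cfg)
  coh <- build_enrollee_years(sim$spans, sim$claims,
                              filter_diagnoses(sim$claims, NULL),
                              specs = list(outcome_spec("total", "total")),
                              deflators = cfg$deflators)
  ey <- coh$years
  # expected annualized spend from the recorded ground truth
  gt <- sim$ground_truth
  row_of <- match(paste(ey$person_id, ey$year),
                  paste(sim$spans$person_id, sim$spans$year))
  item_sum <- rep(0, nrow(ey))
  gs <- gt$item_sets[, .(s = sum(gt$true_beta[item_id])), by = row]
  item_sum[match(gs$row, row_of)] <- gs$s
  cell <- paste0("as_", ey$sex, "_",
                 age_band_labels(default_age_bands())[findInterval(ey$age, default_age_bands())])
  mu <- unname(gt$cell_coefficients[cell]) + item_sum +
    gt$newborn_effect * ey$newborn  # expected_shock is 0 here
  expect_equal(ey$total, mu, tolerance = 1e-8)
})

test_that("realized code frequencies track their targets at scale", {
  cfg <- sim_config(seed = 101, n_persons = 100000L, n_years = 1L)
  mp <- gen_mapping(cfg)
  pop <- gen_population_claims(cfg, mp)
  total_ey <- nrow(pop$spans)
  # compare on the mapped (pre-variant) code: variants resolve by root stem
  realized <- pop$pairs[, .(n = uniqueN(paste(person_id, year))),
                        by = .(root = substr(code, 1, 99))]
  tgt <- mp$codes[, .(code, per_million)]
  realized[, code := root]
  realized[!code %in% tgt$code, code := substr(code, 1, nchar(code) - 1L)]
  realized <- realized[, .(n = sum(n)), by = code]
  cmp <- merge(tgt, realized, by = "code", all.x = TRUE)
  cmp[is.na(n), n := 0L]
  # frequencies are scaled by enrollment fraction; compare against the
  # fraction-adjusted expectation
  eff <- mean(pop$spans$fraction)
  expect_gt(cor(cmp$per_million * eff, cmp$n / total_ey * 1e6), 0.95)
})

test_that("the extreme-episode rate reproduces the intended top-coded share", {
  cfg <- sim_config(seed = 55, n_persons = 20000L, n_years = 1L,
                    extreme_rate = 0.01)
  sim <- simulate_claims(cfg)
  coh <- build_enrollee_years(sim$spans, sim$claims,
                              specs = list(outcome_spec("total", "total",
                                                        analysis_cap = 250000)),
                              deflators = cfg$deflators)
  n <- nrow(coh$years)
  n_capped <- sum(coh$years$total == 250000)
  # an extreme episode exceeds the cap unless its lognormal draw is far below
  # scale: P(topcoded) ~= 0.01 * P(4e5 * LN(0, .25) > ~2.4e5) ~= 0.0098
  bounds <- qbinom(c(1e-5, 1 - 1e-5), n, 0.0098)
  expect_gte(n_capped, bounds[1])
  expect_lte(n_capped, bounds[2])
})

test_that("generated data pass cohort construction cleanly and claims books balance", {
  sim <- simulate_claims(sim_config(seed = 8, n_persons = 2000L))
  expect_no_warning({
    dx <- filter_diagnoses(sim$claims, sim$filter_rules)
    coh <- build_enrollee_years(sim$spans, sim$claims, dx,
                                deflators = sim$config$deflators)
  })
  expect_equal(coh$report$n_orphan_claims, 0L)
  # paid_total = paid_plan + paid_oop line by line
  expect_equal(sim$claims$paid_total, sim$claims$paid_plan + sim$claims$paid_oop,
               tolerance = 1e-9)
  # negative reversals produce floored-to-zero person-years
  rev_ids <- sim$spans$person_id[sim$ground_truth$reversal_rows]
  if (length(rev_ids)) {
    expect_true(all(coh$years[person_id %in% rev_ids & year %in%
                                sim$spans$year[sim$ground_truth$reversal_rows],
                              total] >= 0))
  }
})

test_that("config validation rejects unknown fields and infeasible settings", {
  expect_error(sim_config(nonsense = 1), "unknown sim_config field")
  expect_error(sim_config(overlap_rate = 1.5), "rates")
  expect_error(sim_config(n_codes = 10L, n_main_items = 50L), "n_main_items")
  expect_error(sim_config(n_years = 5L), "deflators")
})
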