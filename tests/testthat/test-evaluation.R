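test_that("weighted fit metrics satisfy their defining identities", {
  set.seed(31)
  y <- rlnorm(50, 7, 1)
  w <- runif(50, 0.2, 1)
  ybar <- sum(w * y) / sum(w)

  expect_equal(weighted_r2(y, y, w), 1)
  expect_equal(weighted_mae(y, y, w), 0)
  expect_equal(weighted_cpm(y, y, w), 1)
  expect_equal(weighted_r2(y, rep(ybar, 50), w), 0)
  expect_equal(weighted_cpm(y, rep(ybar, 50), w), 0)
  expect_equal(weighted_mae(y, y + 42, w), 42)

  # 4-point weighted instance against direct formula evaluation
  y4 <- c(1, 2, 6, 10); yh4 <- c(2, 2, 5, 7); w4 <- c(1, 0.5, 2, 0.25)
  expect_equal(weighted_r2(y4, yh4, w4), r2_oracle(y4, yh4, w4), tolerance = 1e-12)
  expect_equal(weighted_mae(y4, yh4, w4), mae_oracle(y4, yh4, w4), tolerance = 1e-12)
  expect_equal(weighted_cpm(y4, yh4, w4), cpm_oracle(y4, yh4, w4), tolerance = 1e-12)

  # a model worse (in L1) than the weighted-mean predictor goes negative
  yh_bad <- ybar + 5 * (ybar - y)
  expect_lt(weighted_cpm(y, yh_bad, w), 0)

  expect_error(weighted_r2(rep(3, 5), rnorm(5), rep(1, 5)), "variance")
  expect_error(weighted_cpm(rep(3, 5), rnorm(5), rep(1, 5)), "deviation")
})

test_that("weighted metrics reduce to unweighted textbook forms under equal weights", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    y <- rnorm(n, sd = 10)
    yh <- y + rnorm(n, sd = 4)
    expect_equal(weighted_r2(y, yh, rep(2, n)),
                 1 - sum((y - yh)^2) / sum((y - mean(y))^2), tolerance = 1e-12)
    expect_equal(weighted_cpm(y, yh, rep(2, n)),
                 1 - sum(abs(y - yh)) / sum(abs(y - mean(y))), tolerance = 1e-12)
    expect_equal(weighted_mae(y, yh, rep(2, n)), mean(abs(y - yh)), tolerance = 1e-12)
  }
})

test_that("predictive ratios bin by weighted percentiles of actual spending and conserve money", {
  set.seed(33)
  n <- 5000
  y <- rlnorm(n, 8, 1.4)
  w <- runif(n, 1 / 12, 1)

  pr_perfect <- predictive_ratios(y, y, w)
  expect_true(all(abs(pr_perfect$predictive_ratio - 1) < 1e-12))

  # mean-only predictor overpays the bottom, underpays the top on skewed y
  ybar <- sum(w * y) / sum(w)
  pr_null <- predictive_ratios(y, rep(ybar, n), w)
  expect_gt(pr_null$predictive_ratio[1], 1)
  expect_lt(pr_null$predictive_ratio[nrow(pr_null)], 1)

  # conservation: bin-weighted mean actuals aggregate to the overall mean
  expect_equal(sum(pr_null$w_share * pr_null$mean_actual), ybar, tolerance = 1e-9)

  # single bin reproduces overall ratio
  pr1 <- predictive_ratios(y, y * 0.9, w, percentile_edges = numeric(0))
  expect_equal(nrow(pr1), 1L)
  expect_equal(pr1$predictive_ratio, 0.9, tolerance = 1e-12)

  expect_error(predictive_ratios(y, y, w, percentile_edges = c(50, 40)),
               "strictly increasing")
  expect_error(predictive_ratios(y, y, w, percentile_edges = c(0, 50)),
               "strictly increasing")
})

test_that("zero-spending bins report missing predictive ratios", {
  y <- c(0, 0, 10, 10, 20, 40)
  pr <- predictive_ratios(y, y + 1, rep(1, 6), percentile_edges = 50)
  expect_true(is.na(pr$predictive_ratio[1]))
  expect_false(anyNA(pr$predictive_ratio[-1]))
})

test_that("diagnostic frequencies and residual bins follow powers of ten per million", {
  # cohort of 10 enrollee-years with known diagnosis counts
  spans <- make_spans(sprintf("P%02d", 1:10))
  claims <- make_claims(spans$person_id, paid_total = 100,
                        diagnosis_codes = c(rep("A010", 4), rep("B012", 2),
                                            rep("", 4)))
  coh <- build_enrollee_years(spans, claims,
                              specs = list(outcome_spec("total", "total")),
                              deflators = flat_deflators)
  fr <- code_frequencies(coh)
  expect_equal(fr[code == "A010", per_million], 4 / 10 * 1e6)
  expect_equal(attr(fr, "total_enrollee_years"), 10L)

  # a code occurring 3 per million lands in the [1, 10) bin
  fr_fake <- data.table(code = c("A010", "B012"), per_million = c(3, 20000))
  res <- rep(0, 10)
  rb <- residuals_by_frequency(coh, res, fr_fake)
  expect_true("[1,10)" %in% rb$bin)
  expect_true(all(rb$mean_residual == 0))  # perfect model: every bin mean 0

  # one combined bin reproduces the overall weighted mean residual
  res2 <- rnorm(10)
  fr_one <- data.table(code = c("A010", "B012"), per_million = c(5, 5))
  rb2 <- residuals_by_frequency(coh, res2, fr_one)
  pairs_w <- coh$diagnoses[coh$years, on = c("person_id", "year"), nomatch = NULL]
  manual <- pairs_w[, sum(weight * res2[match(paste(person_id, year),
                                              paste(coh$years$person_id, coh$years$year))]) /
                      sum(weight)]
  expect_equal(nrow(rb2), 1L)
  expect_equal(rb2$mean_residual, manual, tolerance = 1e-12)

  # unseen codes drop to the rarest populated bin and are counted
  fr_miss <- data.table(code = "A010", per_million = 3)
  rb3 <- residuals_by_frequency(coh, res, fr_miss)
  expect_equal(attr(rb3, "n_unseen"), 2L)
})

test_that("patient-clustered intervals widen when residuals correlate within person", {
  # two persons, many years each, person-level residual shifts
  n_per <- 30L
  spans <- make_spans(rep(c("A", "B"), each = n_per),
                      year = rep(seq_len(n_per) + 1990L, 2))
  claims <- make_claims(spans$person_id, year = spans$year, paid_total = 10,
                        diagnosis_codes = "A010")
  coh <- build_enrollee_years(spans, claims,
                              specs = list(outcome_spec("total", "total", deflate = FALSE)))
  fr <- code_frequencies(coh)
  res_clustered <- rep(c(5, -5), each = n_per) + rnorm(2 * n_per, sd = 0.1)
  rb <- residuals_by_frequency(coh, res_clustered, fr)
  # with 2 clusters of opposite sign the clustered CI must span ~[-5, 5]
  expect_lt(rb$ci_lo, -3)
  expect_gt(rb$ci_hi, 3)
})

test_that("model comparison requires a common evaluation row set and reports deltas", {
  st <- list()
  set.seed(35)
  spans <- make_spans(sprintf("P%02d", 1:40))
  claims <- make_claims(spans$person_id, paid_total = rlnorm(40, 5, 1),
                        diagnosis_codes = "A010")
  coh <- build_enrollee_years(spans, claims,
                              specs = list(outcome_spec("total", "total")),
                              deflators = flat_deflators)
  m <- toy_mapping()
  spec <- model_spec("total", "dxi")
  d <- build_design(coh, list(dxi = m), spec)
  fit <- wls_fit(d$X, d$y, d$w, model_id = "m1")
  r1 <- evaluate_model(fit, d)
  r2 <- evaluate_model(wls_fit(d$X, d$y, d$w, model_id = "m2"), d)
  cmp <- compare_models(list(r1, r2))
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$delta_r2, c(0, 0))  # identical models: zero deltas
  expect_equal(cmp$delta_mae, c(0, 0))

  d_sub <- build_design(subset_cohort_for_test(coh, sprintf("P%02d", 1:20)),
                        list(dxi = m), spec, columns = colnames(d$X))
  r3 <- evaluate_model(fit, d_sub)
  r3$model_id <- "m3"
  expect_error(compare_models(list(r1, r3)), "different row sets")
})
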