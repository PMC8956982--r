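# Validation-sample model assessment.
#
# All metrics are weight-modified so that partial-year enrollees contribute
# in proportion to their regression weight: weighted R-squared, weighted mean
# absolute error, the weighted Cumming prediction measure (an L1 analogue of
# R-squared), predictive ratios across weighted percentiles of actual
# spending, and mean residuals binned by diagnostic frequency with
# patient-clustered confidence intervals.

#' Weighted R-squared
#'
#' `1 - sum(w (y - yhat)^2) / sum(w (y - ybar_w)^2)` with `ybar_w` the
#' weighted mean of `y`. May be negative out of sample. Reduces to the
#' conventional R-squared under equal weights.
#'
#' @param y actual outcomes.
#' @param yhat predictions.
#' @param w positive weights.
#' @return Scalar.
#' @export
weighted_r2 <- function(y, yhat, w = rep(1, length(y))) {
  stopifnot(length(y) == length(yhat), length(y) == length(w), all(w > 0))
  ybar <- wmean(y, w)
  tss <- sum(w * (y - ybar)^2)
  if (tss <= 0) stop("outcome has zero weighted variance")
  1 - sum(w * (y - yhat)^2) / tss
}

#' Weighted mean absolute error
#'
#' `sum(w |y - yhat|) / sum(w)`, in outcome units.
#'
#' @inheritParams weighted_r2
#' @return Scalar.
#' @export
weighted_mae <- function(y, yhat, w = rep(1, length(y))) {
  stopifnot(length(y) == length(yhat), length(y) == length(w))
  wmean(abs(y - yhat), w)
}

#' Weighted Cumming prediction measure
#'
#' `1 - sum(w |y - yhat|) / sum(w |y - ybar_w|)`: one minus the ratio of the
#' weighted mean absolute error to the weighted mean absolute deviation from
#' the weighted mean. Like R-squared it equals 1 for a perfect fit and 0 for
#' the weighted-mean predictor, but it can go negative when a model does
#' worse than that null predictor in L1. The null predictor's mean is taken
#' from the evaluation sample itself.
#'
#' @inheritParams weighted_r2
#' @return Scalar, at most 1.
#' @export
weighted_cpm <- function(y, yhat, w = rep(1, length(y))) {
  stopifnot(length(y) == length(yhat), length(y) == length(w), all(w > 0))
  ybar <- wmean(y, w)
  denom <- sum(w * abs(y - ybar))
  if (denom <= 0) stop("outcome has zero weighted absolute deviation")
  1 - sum(w * abs(y - yhat)) / denom
}

#' Predictive ratios across percentiles of actual outcome
#'
#' Rows are binned by weighted percentiles (type-1, lower-edge inclusive) of
#' the *actual* outcome; each bin reports the weighted mean actual, weighted
#' mean predicted, and their ratio (predicted / actual; 1.0 indicates
#' unbiased group-level payment). Bins with zero mean actual report `NA`.
#'
#' @inheritParams weighted_r2
#' @param percentile_edges increasing percentile cut points strictly inside
#'   (0, 100); the default gives bins 0-50, 50-75, 75-90, 90-95, 95-99,
#'   99-100.
#' @return data.table: `bin`, `w_share`, `mean_actual`, `mean_predicted`,
#'   `predictive_ratio`.
#' @export
predictive_ratios <- function(y, yhat, w = rep(1, length(y)),
                              percentile_edges = c(50, 75, 90, 95, 99)) {
  stopifnot(length(y) == length(yhat), length(y) == length(w))
  if (length(percentile_edges)) {
    if (any(percentile_edges <= 0 | percentile_edges >= 100) ||
        is.unsorted(percentile_edges, strictly = TRUE)) {
      stop("percentile_edges must be strictly increasing within (0, 100)")
    }
    cuts <- weighted_quantile(y, w, percentile_edges / 100)
    # lower-edge inclusive bins on the actual outcome
    bin_idx <- findInterval(y, unique(cuts), left.open = FALSE) + 1L
    edges_lab <- c(0, percentile_edges, 100)
    labs <- sprintf("p%g-%g", edges_lab[-length(edges_lab)], edges_lab[-1L])
    labs <- labs[seq_len(length(unique(cuts)) + 1L)]
  } else {
    bin_idx <- rep(1L, length(y))
    labs <- "p0-100"
  }
  dt <- data.table(bin = labs[bin_idx], y = y, yhat = yhat, w = w)
  out <- dt[, .(w_share = sum(w), mean_actual = sum(w * y) / sum(w),
                mean_predicted = sum(w * yhat) / sum(w)), by = bin]
  out[, w_share := w_share / sum(w_share)]
  out[, predictive_ratio := fifelse(mean_actual != 0,
                                    mean_predicted / mean_actual, NA_real_)]
  out[order(match(bin, labs))][]
}

#' Diagnostic frequencies in a reference sample
#'
#' Counts, per distinct diagnosis code, the number of enrollee-years carrying
#' it, expressed per million enrollee-years. Frequencies are meant to be
#' computed on the designated full sample (development plus validation,
#' before splitting).
#'
#' @param cohort a `dxi_cohort`.
#' @return data.table: `code`, `n_years`, `per_million`; attribute
#'   `total_enrollee_years`.
#' @export
code_frequencies <- function(cohort) {
  stopifnot(inherits(cohort, "dxi_cohort"))
  total <- nrow(cohort$years)
  out <- cohort$diagnoses[, .(n_years = .N), by = code]
  out[, per_million := n_years / total * 1e6]
  setattr(out, "total_enrollee_years", total)
  out[]
}

# half-open power-of-ten bin index of a per-million frequency
freq_bin_index <- function(per_million) as.integer(floor(log10(per_million)))

freq_bin_label <- function(k) {
  sprintf("[%s,%s)", format(10^k, scientific = FALSE, trim = TRUE),
          format(10^(k + 1), scientific = FALSE, trim = TRUE))
}

#' Mean residuals by diagnostic frequency
#'
#' Each (enrollee-year, distinct diagnosis) pair contributes that
#' enrollee-year's residual, with its regression weight, to the frequency
#' bin of the diagnosis; bins are half-open powers of ten per million
#' enrollee-years in the reference sample. Per bin the weighted mean residual
#' is reported with a 95% confidence interval corrected for clustering at the
#' patient level: each person's weighted contributions are aggregated first
#' and the variance of the weighted mean is taken across persons.
#'
#' Large mean residuals in rare bins signal diagnoses whose cost consequences
#' the classification cannot see — enrollees a payer could profitably avoid.
#'
#' @param cohort a `dxi_cohort` (the sample on which residuals are
#'   evaluated, typically the validation sample).
#' @param residuals numeric vector aligned with `cohort$years` rows
#'   (actual minus predicted).
#' @param frequencies output of [code_frequencies()] on the reference
#'   sample. Codes absent from it are assigned to the rarest populated bin
#'   and counted in the `n_unseen` attribute.
#' @return data.table: `bin`, `per_million_lo`, `per_million_hi`,
#'   `mean_residual`, `ci_lo`, `ci_hi`, `n_pairs`, `n_years`, `n_codes`,
#'   sorted rare to common.
#' @export
residuals_by_frequency <- function(cohort, residuals, frequencies) {
  stopifnot(inherits(cohort, "dxi_cohort"),
            length(residuals) == nrow(cohort$years))
  ey <- cohort$years[, .(person_id, year, weight)]
  ey[, residual := residuals]
  pairs <- merge(cohort$diagnoses, ey, by = c("person_id", "year"))
  pairs <- merge(pairs, frequencies[, .(code, per_million)], by = "code",
                 all.x = TRUE)
  n_unseen <- sum(is.na(pairs$per_million))
  kmin <- if (all(is.na(pairs$per_million))) 0L else
    freq_bin_index(min(pairs$per_million, na.rm = TRUE))
  pairs[, k := fifelse(is.na(per_million), kmin, freq_bin_index(per_million))]

  bins <- pairs[, {
    agg <- .SD[, .(s = sum(weight * residual), sw = sum(weight)), by = person_id]
    m <- sum(agg$s) / sum(agg$sw)
    G <- nrow(agg)
    v <- if (G > 1L) G / (G - 1L) * sum((agg$s - m * agg$sw)^2) / sum(agg$sw)^2 else NA_real_
    .(mean_residual = m,
      ci_lo = m - 1.96 * sqrt(v), ci_hi = m + 1.96 * sqrt(v),
      n_pairs = .N, n_years = uniqueN(paste(person_id, year)),
      n_codes = uniqueN(code))
  }, by = k]
  setorder(bins, k)
  bins[, bin := freq_bin_label(k)]
  bins[, `:=`(per_million_lo = 10^k, per_million_hi = 10^(k + 1), k = NULL)]
  setcolorder(bins, c("bin", "per_million_lo", "per_million_hi",
                      "mean_residual", "ci_lo", "ci_hi",
                      "n_pairs", "n_years", "n_codes"))
  setattr(bins, "n_unseen", n_unseen)
  bins[]
}

#' Evaluate a fitted model on a sample
#'
#' Convenience wrapper computing the full metric battery on one design.
#'
#' @param fit a `dxi_fit`.
#' @param design a `dxi_design` built on the evaluation sample (with the
#'   development column set).
#' @param percentile_edges passed to [predictive_ratios()].
#' @return List of class `dxi_eval`: `model_id`, `n`, `n_columns`,
#'   `weighted_r2`, `weighted_mae`, `weighted_cpm`, `negative_share`,
#'   `percentile_table`, plus the prediction vector in `yhat`.
#' @export
evaluate_model <- function(fit, design, percentile_edges = c(50, 75, 90, 95, 99)) {
  pred <- predict(fit, design)
  y <- design$y
  w <- design$w
  structure(list(
    model_id = fit$model_id %||% "model",
    n = length(y),
    n_columns = length(fit$coefficients),
    weighted_r2 = weighted_r2(y, pred$yhat, w),
    weighted_mae = weighted_mae(y, pred$yhat, w),
    weighted_cpm = weighted_cpm(y, pred$yhat, w),
    negative_share = pred$negative_share,
    percentile_table = predictive_ratios(y, pred$yhat, w, percentile_edges),
    yhat = pred$yhat,
    row_key = fnv1a(paste(design$index$person_id, design$index$year, collapse = "|"))
  ), class = "dxi_eval")
}

#' @export
print.dxi_eval <- function(x, ...) {
  cat(sprintf("<dxi_eval %s> n=%d, cols=%d, R2=%.4f, MAE=%.2f, CPM=%.4f, negative share=%.4f\n",
              x$model_id, x$n, x$n_columns, x$weighted_r2, x$weighted_mae,
              x$weighted_cpm, x$negative_share))
  invisible(x)
}

#' Compare evaluation reports side by side
#'
#' @param reports list of `dxi_eval` objects computed on the same evaluation
#'   rows (enforced via a row-set fingerprint).
#' @return data.table: one row per model with the headline metrics and
#'   deltas against the first (base) model.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "dxi_eval")))
  keys <- vapply(reports, `[[`, "", "row_key")
  if (length(unique(keys)) > 1L) {
    stop("evaluation reports were computed on different row sets")
  }
  out <- rbindlist(lapply(reports, function(r) {
    data.table(model = r$model_id, n = r$n, n_columns = r$n_columns,
               weighted_r2 = r$weighted_r2, weighted_mae = r$weighted_mae,
               weighted_cpm = r$weighted_cpm, negative_share = r$negative_share)
  }))
  out[, `:=`(delta_r2 = weighted_r2 - weighted_r2[1L],
             delta_mae = weighted_mae - weighted_mae[1L],
             delta_cpm = weighted_cpm - weighted_cpm[1L])]
  out[]
}
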