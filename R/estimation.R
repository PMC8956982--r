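# Weighted least squares and forward-stepwise selection.
#
# The numerical core works on the weighted Gram system A = X'WX, b = X'Wy.
# A sequential Cholesky factorization adds columns in order and drops a
# column whenever its pivot collapses (relative tolerance), which gives the
# deterministic "first kept wins" rule for collinear columns. The stepwise
# selector reuses the same factorization: single-column entry statistics for
# all candidates are obtained from one triangular solve per step.

.PIVOT_TOL <- 1e-9

# Sequential Cholesky of A over columns `order`, dropping collinear columns.
# Returns kept indices (in entry order) and the lower-triangular factor L.
chol_sequential <- function(A, order = seq_len(ncol(A)), tol = .PIVOT_TOL) {
  p <- length(order)
  L <- matrix(0, p, p)
  kept <- integer(0)
  for (j in order) {
    k <- length(kept)
    r <- if (k) forwardsolve(L[seq_len(k), seq_len(k), drop = FALSE], A[kept, j]) else numeric(0)
    d <- A[j, j] - sum(r * r)
    if (!is.finite(d) || d <= tol * max(A[j, j], 1)) next
    kept <- c(kept, j)
    k <- k + 1L
    if (k > 1L) L[k, seq_len(k - 1L)] <- r
    L[k, k] <- sqrt(d)
  }
  list(kept = kept, L = L[seq_along(kept), seq_along(kept), drop = FALSE])
}

#' Weighted least-squares fit
#'
#' Minimizes the weighted residual sum of squares `sum(w * (y - X b)^2)` and
#' reports classical WLS standard errors and two-sided t-test p-values.
#' Collinear columns are dropped deterministically (the first column in
#' matrix order is kept) and recorded in `dropped`.
#'
#' @param X design matrix (dense or `Matrix` sparse) with column names.
#' @param y outcome vector.
#' @param w positive weights.
#' @param model_id optional label carried into evaluation reports.
#' @return A `dxi_fit`: named `coefficients`, `se`, `p_values`, weighted
#'   training `r2`, residual variance `sigma2`, degrees of freedom,
#'   `dropped` columns, `n`, and (for stepwise fits) a selection `trace`.
#' @export
wls_fit <- function(X, y, w = rep(1, length(y)), model_id = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L, dimnames = list(NULL, "x"))
  n <- nrow(X)
  if (n == 0L) stop("cannot fit on zero rows")
  if (length(y) != n || length(w) != n) stop("X, y, w must have aligned rows")
  if (any(!is.finite(y)) || any(!is.finite(w))) stop("non-finite values in y or w")
  if (any(w <= 0)) stop("weights must be strictly positive")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  A <- as.matrix(Matrix::crossprod(X, w * X))
  b <- as.numeric(Matrix::crossprod(X, w * y))
  fac <- chol_sequential(A)
  kept <- fac$kept
  if (!length(kept)) stop("design matrix has no usable columns")
  z <- forwardsolve(fac$L, b[kept])
  beta <- backsolve(t(fac$L), z)
  resid <- as.numeric(y - X[, kept, drop = FALSE] %*% beta)
  rss <- sum(w * resid^2)
  df <- n - length(kept)
  sigma2 <- if (df > 0) rss / df else NA_real_
  cov_unscaled <- chol2inv(t(fac$L))
  se <- sqrt(pmax(diag(cov_unscaled), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = max(df, 1L))
  ybar <- wmean(y, w)
  tss <- sum(w * (y - ybar)^2)
  cols <- colnames(X)[kept]
  structure(list(
    coefficients = setNames(as.numeric(beta), cols),
    se = setNames(as.numeric(se), cols),
    p_values = setNames(as.numeric(pval), cols),
    r2 = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma2 = sigma2, rss = rss, df_residual = df, n = n,
    dropped = colnames(X)[setdiff(seq_len(ncol(X)), kept)],
    trace = NULL, model_id = model_id,
    settings = list()
  ), class = "dxi_fit")
}

#' @export
print.dxi_fit <- function(x, ...) {
  cat(sprintf("<dxi_fit%s> %d coefficients (%d dropped), n=%d, weighted R2=%.4f\n",
              if (is.null(x$model_id)) "" else paste0(" ", x$model_id),
              length(x$coefficients), length(x$dropped), x$n, x$r2))
  if (!is.null(x$trace)) {
    cat(sprintf("  stepwise: %d steps, entry p<%g\n", nrow(x$trace),
                x$settings$entry_p))
  }
  invisible(x)
}

#' @export
coef.dxi_fit <- function(object, ...) object$coefficients

#' Forward-stepwise weighted least squares
#'
#' Starts from the forced base (typically the age-sex block, which is never
#' eligible for removal). At each step the candidate whose single-column
#' addition has the smallest p-value is entered if that p-value is below
#' `entry_p`; ties break on the lexicographically smallest column name.
#' After each entry, previously entered (non-forced) columns whose current
#' p-value has risen to `stay_p` or above are removed, worst first. The
#' procedure stops when no candidate qualifies, when a removal would
#' immediately be re-entered, or when residual degrees of freedom are
#' exhausted.
#'
#' @param X design matrix with column names.
#' @param y,w outcome and positive weights.
#' @param entry_p entry threshold in (0, 1]; a candidate enters only if its
#'   p-value is strictly below it.
#' @param stay_p removal threshold (defaults to `entry_p`).
#' @param forced character vector of column names always retained.
#' @param removal logical; allow removal of entered columns (default TRUE).
#' @param model_id optional label.
#' @return A `dxi_fit` on the selected columns, with `trace` (step, action,
#'   column, p_value) and `settings` recording the thresholds.
#' @export
stepwise_fit <- function(X, y, w = rep(1, length(y)), entry_p = 1e-4,
                         stay_p = entry_p, forced = character(),
                         removal = TRUE, model_id = NULL) {
  if (!(entry_p > 0 && entry_p <= 1)) stop("entry_p must lie in (0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(bad <- setdiff(forced, colnames(X)))) {
    stop("forced column(s) not in X: ", paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  cols <- colnames(X)
  A <- as.matrix(Matrix::crossprod(X, w * X))
  b <- as.numeric(Matrix::crossprod(X, w * y))
  syy <- sum(w * y^2)

  forced_idx <- which(cols %in% forced)
  fac <- chol_sequential(A, order = forced_idx)
  S <- fac$kept                       # selected, in entry order
  candidates <- setdiff(seq_along(cols), forced_idx)

  trace <- list()
  step <- 0L
  last_removed <- NA_integer_
  repeat {
    k <- length(S)
    if (!length(candidates) || n - k - 1L < 1L) break
    L <- chol_sequential(A, order = S)$L
    z <- forwardsolve(L, b[S])
    rss_S <- max(syy - sum(z * z), 0)

    Rall <- forwardsolve(L, A[S, candidates, drop = FALSE])
    d <- diag(A)[candidates] - colSums(Rall^2)
    valid <- is.finite(d) & d > .PIVOT_TOL * pmax(diag(A)[candidates], 1)
    if (!any(valid)) break
    q <- rep(NA_real_, length(candidates))
    q[valid] <- (b[candidates][valid] - as.numeric(crossprod(Rall[, valid, drop = FALSE], z))) /
      sqrt(d[valid])
    df_new <- n - k - 1L
    sigma2_new <- pmax(rss_S - q^2, 0) / df_new
    tstat <- ifelse(sigma2_new > 0, abs(q) / sqrt(sigma2_new), Inf)
    pvals <- ifelse(is.finite(tstat), 2 * pt(-tstat, df_new), 0)
    pvals[!valid] <- NA_real_

    ord <- order(pvals, cols[candidates], na.last = TRUE)
    best <- candidates[ord[1L]]
    best_p <- pvals[ord[1L]]
    if (!is.finite(best_p) || best_p >= entry_p) break
    if (identical(best, last_removed)) break  # entry/removal stall
    S <- c(S, best)
    candidates <- setdiff(candidates, best)
    step <- step + 1L
    trace[[length(trace) + 1L]] <- data.table(step = step, action = "enter",
                                              column = cols[best], p_value = best_p)

    if (removal) {
      repeat {
        fit_S <- .gram_pvalues(A, b, syy, S, n)
        removable <- setdiff(S, forced_idx)
        if (!length(removable)) break
        pv <- fit_S$p[match(removable, S)]
        worst <- which.max(pv)
        if (!length(worst) || is.na(pv[worst]) || pv[worst] < stay_p) break
        out <- removable[worst]
        S <- setdiff(S, out)
        candidates <- c(candidates, out)
        last_removed <- out
        step <- step + 1L
        trace[[length(trace) + 1L]] <- data.table(step = step, action = "remove",
                                                  column = cols[out], p_value = pv[worst])
      }
    }
  }

  fit <- wls_fit(X[, S, drop = FALSE], y, w, model_id = model_id)
  fit$trace <- if (length(trace)) rbindlist(trace) else
    data.table(step = integer(), action = character(),
               column = character(), p_value = numeric())
  fit$settings <- list(entry_p = entry_p, stay_p = stay_p,
                       forced = cols[forced_idx], removal = removal)
  fit
}

# coefficient p-values for the subset S from the Gram system only
.gram_pvalues <- function(A, b, syy, S, n) {
  L <- chol_sequential(A, order = S)$L
  z <- forwardsolve(L, b[S])
  beta <- backsolve(t(L), z)
  rss <- max(syy - sum(z * z), 0)
  df <- n - length(S)
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- sqrt(pmax(diag(chol2inv(t(L))), 0) * sigma2)
  tval <- ifelse(se > 0, beta / se, Inf)
  list(beta = beta, se = se,
       p = 2 * pt(-abs(tval), df = max(df, 1L)))
}

#' Bonferroni-corrected significance flags
#'
#' Flags coefficients whose p-value is strictly below
#' `min(alpha / m, ceiling)`, where `m` is the size of the tested family
#' (default: all candidate columns considered, not only those retained) and
#' `ceiling` is a fixed cap on the threshold.
#'
#' @param fit a `dxi_fit`.
#' @param alpha family-wise error rate (default 0.05).
#' @param m family size; must be positive.
#' @param ceiling upper bound on the per-test threshold (default `1e-4`).
#' @return Named logical vector, one flag per retained coefficient.
#' @export
significance_flags <- function(fit, alpha = 0.05, m = length(fit$p_values),
                               ceiling = 1e-4) {
  stopifnot(inherits(fit, "dxi_fit"))
  if (m <= 0) stop("family size m must be positive")
  threshold <- min(alpha / m, ceiling)
  fit$p_values < threshold
}

#' Predict from a fitted model
#'
#' Predictions are the linear index `X b`; negative values are preserved
#' (they reflect the net effect of collinear diagnostic coefficients) and
#' their weighted share is reported.
#'
#' @param object a `dxi_fit`.
#' @param design a `dxi_design` whose columns include every model column, or
#'   a plain matrix.
#' @param ... unused.
#' @return List of class `dxi_predictions`: `yhat`, `negative_share`
#'   (weighted fraction of rows with a negative prediction), `index`, `w`.
#' @export
predict.dxi_fit <- function(object, design, ...) {
  if (inherits(design, "dxi_design")) {
    X <- design$X
    w <- design$w
    index <- design$index
  } else {
    X <- design
    w <- rep(1, nrow(X))
    index <- NULL
  }
  cols <- names(object$coefficients)
  missing_cols <- setdiff(cols, colnames(X))
  if (length(missing_cols)) {
    stop("design lacks model column(s): ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  }
  yhat <- as.numeric(X[, cols, drop = FALSE] %*% object$coefficients)
  structure(list(yhat = yhat,
                 negative_share = sum(w[yhat < 0]) / sum(w),
                 index = index, w = w),
            class = "dxi_predictions")
}

#' Serialize a fitted model to JSON
#'
#' Coefficients, standard errors, p-values, selection trace and settings are
#' written so evaluation can reuse a fit without re-estimating.
#'
#' @param fit a `dxi_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  out <- list(model_id = fit$model_id, n = fit$n, r2 = fit$r2,
              sigma2 = fit$sigma2, df_residual = fit$df_residual,
              columns = names(fit$coefficients),
              coefficients = unname(fit$coefficients),
              se = unname(fit$se), p_values = unname(fit$p_values),
              dropped = fit$dropped, settings = fit$settings,
              trace = fit$trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized fit
#'
#' @param path path written by [write_fit()].
#' @return A `dxi_fit`.
#' @export
read_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = setNames(raw$coefficients, raw$columns),
    se = setNames(raw$se, raw$columns),
    p_values = setNames(raw$p_values, raw$columns),
    r2 = raw$r2, sigma2 = raw$sigma2, rss = NA_real_,
    df_residual = raw$df_residual, n = raw$n,
    dropped = raw$dropped %||% character(),
    trace = if (!is.null(raw$trace)) as.data.table(raw$trace) else NULL,
    model_id = raw$model_id, settings = raw$settings %||% list()
  ), class = "dxi_fit")
}
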