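# Small shared helpers (seed scoping, weighted quantiles, hashing).

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a base seed, staying within the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

#' Weighted quantiles (type 1)
#'
#' Lower-edge-inclusive, interpolation-free weighted quantiles: the smallest
#' observed value whose cumulative normalized weight reaches `probs`. With
#' equal weights this coincides with `stats::quantile(type = 1)`.
#'
#' @param x numeric values.
#' @param w positive weights, same length as `x`.
#' @param probs probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0 & probs <= 1))
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(xs[1L])
    xs[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

# Weighted mean with explicit zero-weight guard.
wmean <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) stop("total weight must be positive")
  sum(w * x) / sw
}

# Deterministic FNV-1a hash of a character scalar; used for config hashes in
# run manifests (content fingerprint, not cryptographic).
fnv1a <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
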