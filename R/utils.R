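#' Round a percentage to the nearest integer, halves away from zero
#'
#' Reported recurrence and hit-rate percentages are rounded to the nearest
#' whole percent, with exact halves rounded away from zero (so 5.5 -> 6),
#' rather than the round-half-even rule of [base::round()].
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @return Integer percentage `round(100 * numerator / denominator)` with
#'   half-away-from-zero rounding.
#' @examples
#' pct_round(431, 7430)  # 6
#' pct_round(1, 8)       # 13 (12.5 rounds up)
#' @export
pct_round <- function(numerator, denominator) {
  stopifnot(length(denominator) == 1L || length(denominator) == length(numerator))
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Plus-one empirical p-value
#'
#' Permutation p-value with plus-one smoothing: `(1 + b) / (1 + R)` where
#' `b` is the number of null statistics at least as extreme as the observed
#' one and `R` the number of permutations. Never returns 0.
#'
#' @param n_exceed Number of null draws at least as extreme as observed.
#' @param n_perm Number of permutations.
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(n_exceed, n_perm) {
  stopifnot(n_perm >= 1, n_exceed >= 0, n_exceed <= n_perm)
  (1 + n_exceed) / (1 + n_perm)
}

# Sample standard deviation of matrix rows; rows with < 2 finite values or
# zero spread get sd 0 (callers map that to z = 0).
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (n - 1L)
  sqrt(pmax(v, 0))
}

# Derive a stage seed from a global seed by a fixed offset, kept within the
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
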