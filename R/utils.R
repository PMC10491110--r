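# Internal helpers shared across modules.

#' @useDynLib filmsens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_filmsens <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "filmsens_error")))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_filmsens("`%s` must be a single finite number", name,
                  class = "filmsens_domain_error")
  invisible(x)
}

# Row-broadcast a vector over an n-row matrix (adding a bias, scaling by a
# per-column factor, ...): column-major recycling, so `M op bcast(v, nrow(M))`
# applies v across columns. Much cheaper than matrix(byrow = TRUE) or sweep().
bcast <- function(v, n) rep(v, each = n)

col_vars <- function(x) {
  # biased (1/n) column variances, as used by batch normalization
  colMeans(x * x) - colMeans(x)^2
}

#' Coefficient of determination
#'
#' Computes R-squared as 1 - SS_res / SS_tot between predictions and observed
#' values. Used as the validation metric during model training.
#'
#' @param predictions Numeric vector of predicted values.
#' @param truths Numeric vector of observed values, same length.
#' @return A single number, at most 1. Negative values indicate predictions
#'   worse than the mean of `truths`.
#' @export
r_squared <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0L)
    stop_filmsens("predictions and truths must have equal, nonzero length",
                  class = "filmsens_shape_error")
  ss_tot <- sum((truths - mean(truths))^2)
  if (ss_tot == 0)
    stop_filmsens("truths are constant: R-squared denominator is undefined",
                  class = "filmsens_domain_error")
  1 - sum((truths - predictions)^2) / ss_tot
}

# Deterministic sub-seed derivation; keeps derived seeds in 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1009L
}
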