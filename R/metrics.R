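#' Coefficient of determination on held-out data
#'
#' \eqn{R^2 = 1 - \sum_i (\hat y_i - y_i)^2 / \sum_i (y_i - \bar y)^2}.
#' Can be negative when predictions are worse than the mean of the observed
#' values (common for extrapolating tree models on small test sets).
#'
#' @param y_true observed values.
#' @param y_pred predicted values, same length.
#' @return scalar R-squared.
#' @export
r2_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2)
    jf_stop("jf_parameter_error", "r2_score needs two equal-length vectors, n >= 2")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst <= 0)
    jf_stop("jf_degenerate_error", "r2_score undefined for constant y_true")
  1 - sum((y_pred - y_true)^2) / sst
}

#' Root mean square error of prediction
#'
#' @param y_true observed values (mg/L).
#' @param y_pred predicted values.
#' @return RMSE in the units of `y_true`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    jf_stop("jf_parameter_error", "rmse needs two equal-length non-empty vectors")
  sqrt(mean((y_pred - y_true)^2))
}

#' Residual prediction difference
#'
#' `RPD = 1 / sqrt(1 - Rp2)`, the standard chemometric identity between RPD
#' (sd of reference values over prediction error) and test-set R-squared.
#' Values above 2.4 are conventionally considered robust.
#'
#' @param rp2 test-set R-squared, must be < 1.
#' @return RPD (>= 1 when `0 <= rp2 < 1`).
#' @export
rpd <- function(rp2) {
  if (!is.finite(rp2) || rp2 >= 1)
    jf_stop("jf_domain_error", "rpd requires rp2 < 1 (got %s)", format(rp2))
  1 / sqrt(1 - rp2)
}

# total-function variant used inside the pipeline: perfect fits (exact
# replicate splits at zero noise) map to Inf instead of erroring
rpd_safe <- function(rp2) {
  if (!is.finite(rp2)) return(NA_real_)
  if (rp2 >= 1) return(Inf)
  1 / sqrt(1 - rp2)
}
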