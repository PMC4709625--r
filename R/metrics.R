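#' Figures of merit for calibration and prediction
#'
#' The standard chemometric error measures. `rmse()` is the root mean
#' square error \eqn{\sqrt{\sum_i(\hat y_i - y_i)^2/n}} (RMSEC on the
#' calibration set, RMSEP on the prediction set). `rse()` is the
#' relative standard error in percent, the RMS residual normalized by
#' the RMS of the reference values:
#' \eqn{100\sqrt{\sum_i(\hat y_i - y_i)^2 / \sum_i y_i^2}} (RSEC/RSEP).
#' `r_squared()` is the coefficient of determination
#' \eqn{1 - \sum(\hat y - y)^2/\sum(y - \bar y)^2}.
#'
#' @param y reference values (mg/mL).
#' @param yhat predicted values, same length.
#' @return A single number: mg/mL for `rmse`, percent for `rse`,
#'   a fraction for `r_squared`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 1) stop("need at least one pair")
  sqrt(mean((yhat - y)^2))
}

#' @rdname rmse
#' @export
rse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (sum(y^2) == 0) stop("all-zero reference values")
  100 * sqrt(sum((yhat - y)^2) / sum(y^2))
}

#' @rdname rmse
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (stats::sd(y) == 0) stop("constant y")
  1 - sum((yhat - y)^2) / sum((y - mean(y))^2)
}

#' Ratio of performance to deviation
#'
#' RPD = sample standard deviation (n-1 denominator) of the reference
#' concentrations divided by the model's RMSE. Values above 3 are
#' conventionally considered good for quantitative prediction.
#'
#' @param y_ref reference concentrations of the set (>= 2 values,
#'   non-constant).
#' @param rmse_value the corresponding RMSE (> 0).
#' @return Dimensionless ratio.
#' @export
rpd <- function(y_ref, rmse_value) {
  if (length(y_ref) < 2) stop("need at least 2 reference values")
  s <- stats::sd(y_ref)
  if (s == 0) stop("constant reference set")
  if (rmse_value == 0) stop("perfect fit, RPD undefined")
  s / rmse_value
}

#' Batch-to-batch summary statistics
#'
#' Arithmetic mean and relative standard deviation
#' (RSD = 100 * sample SD / mean) of end-of-process concentrations
#' across batches.
#'
#' @param values numeric vector of per-batch values (>= 2).
#' @return List with `mean` and `rsd` (percent).
#' @export
batch_summary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  list(mean = m, rsd = 100 * stats::sd(values) / m)
}

#' Model acceptance rule for on-line prediction
#'
#' A calibration model is accepted for on-line use when its relative
#' standard error of prediction is below 20 percent and its RPD of
#' prediction is above 3.0 (both strict).
#'
#' @param rsep relative standard error of prediction, percent.
#' @param rpd ratio of performance to deviation.
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   empty when passing).
#' @export
acceptance_check <- function(rsep, rpd) {
  if (!is.finite(rsep) || !is.finite(rpd))
    stop("rsep and rpd must be finite")
  reasons <- character(0)
  if (!(rsep < 20))
    reasons <- c(reasons, sprintf("RSEP %.4g%% is not below 20%%", rsep))
  if (!(rpd > 3))
    reasons <- c(reasons, sprintf("RPD %.4g is not above 3.0", rpd))
  list(pass = length(reasons) == 0, reasons = reasons)
}
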