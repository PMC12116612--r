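#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))`, in the units of the outcome.
#'
#' @param y,yhat numeric vectors of equal nonzero length.
#' @return nonnegative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    abort_semg("rmse needs equal, nonzero-length vectors",
               "semgcobb_bad_metric_input")
  }
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`. Negative values indicate a fit worse than
#' predicting the mean; `y` must not be constant.
#'
#' @param y,yhat numeric vectors of equal nonzero length.
#' @return scalar <= 1.
#' @export
r2 <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    abort_semg("r2 needs equal, nonzero-length vectors",
               "semgcobb_bad_metric_input")
  }
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    abort_semg("r2 undefined for constant y (zero variance)",
               "semgcobb_constant_y")
  }
  1 - sum((y - yhat)^2) / sstot
}
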