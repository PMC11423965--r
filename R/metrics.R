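#' Single-point temperature prediction errors
#'
#' `mae()` is the mean absolute error `(1/n) * sum(|y - yhat|)`; `rmse()`
#' is the root mean square error `sqrt(mean((y - yhat)^2))`. RMSE is never
#' smaller than MAE.
#'
#' @param y actual temperatures.
#' @param yhat predicted temperatures, same length.
#' @return non-negative scalar, degC.
#' @export
mae <- function(y, yhat) {
  check_pair(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname mae
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

check_pair <- function(y, yhat) {
  if (length(y) == 0) stop_domain("empty input")
  if (length(y) != length(yhat)) {
    stop_domain("y and yhat must have the same length (", length(y),
                " vs ", length(yhat), ")")
  }
  invisible(NULL)
}

#' Linear correlation between a texture feature and temperature
#'
#' Pearson correlation, used to report how the selected features track
#' temperature (e.g. patch minimum rises while variance, mean absolute
#' deviation and cluster prominence fall during heating). A constant
#' series has no defined correlation and returns `NA` with a warning.
#'
#' @param feature numeric feature series.
#' @param temperature matching temperature series (n >= 3).
#' @return Pearson r, or `NA` if undefined.
#' @export
feature_temperature_correlation <- function(feature, temperature) {
  check_pair(feature, temperature)
  if (length(feature) < 3) stop_domain("need at least 3 observations")
  if (stats::sd(feature) == 0 || stats::sd(temperature) == 0) {
    warning("correlation undefined for a constant series")
    return(NA_real_)
  }
  stats::cor(feature, temperature)
}
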