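#' Prediction metrics
#'
#' \code{rSquared} is the prediction-based coefficient of determination
#' \code{1 - SSE/SST} (not a squared correlation); it can be negative when
#' predictions are worse than the mean. \code{rmse} is the root-mean-square
#' error in the response's units.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return A single number.
#' @export
rSquared <- function(y, yhat) 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)

#' @rdname rSquared
#' @export
rmse <- function(y, yhat) sqrt(mean((yhat - y)^2))

#' Round half away from zero
#'
#' Commercial rounding used when rendering report percentages (base R's
#' \code{round} rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return Rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' RMSE as percent of the reference maximum
#'
#' The reporting convention for model-quality tables:
#' \code{100 * rmse / max(ref)}. Rendered values are rounded half-up to one
#' decimal (use \code{\link{roundHalfUp}} or \code{\link{formatRmseCell}}).
#'
#' @param rmse RMSE in analyte units.
#' @param refValues reference values of the analyte (max must be > 0).
#' @return Percent, full precision.
#' @export
rmsePctOfMax <- function(rmse, refValues) {
  mx <- max(refValues, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("domain error: max of reference values must be > 0")
  100 * rmse / mx
}

#' Render an "RMSE (percent-of-max)" table cell
#'
#' @param rmse RMSE in analyte units.
#' @param refValues reference values of the analyte.
#' @return Character like \code{"1.78 (3.4\%)"}.
#' @export
formatRmseCell <- function(rmse, refValues) {
  sprintf("%.2f (%.1f%%)", rmse,
          roundHalfUp(rmsePctOfMax(rmse, refValues), 1))
}

#' Validate a calibration model on an independent test set
#'
#' Applies the model unchanged to test spectra (already preprocessed with
#' the model's recipe) and reports plug-in R^2 and RMSE against the test
#' reference values. Pairs with a missing reference value are dropped.
#'
#' @param m a \linkS4class{CalibrationModel}.
#' @param Xtest numeric matrix on the model's channel layout.
#' @param yTest numeric reference values (NA allowed, dropped pairwise).
#' @return A \linkS4class{ValidationReport} with \code{kind = "test"}.
#' @export
validateOnTest <- function(m, Xtest, yTest) {
  stopifnot(is(m, "CalibrationModel"))
  Xtest <- as.matrix(Xtest)
  ok <- !is.na(yTest)
  Xtest <- Xtest[ok, , drop = FALSE]; yTest <- yTest[ok]
  if (!length(yTest)) stop("validation error: empty test set")
  yhat <- plsrPredict(m, Xtest)
  e <- rmse(yTest, yhat)
  new("ValidationReport", r2 = rSquared(yTest, yhat), rmse = e,
      rmsePctOfMax = rmsePctOfMax(e, yTest), n = length(yTest),
      kind = "test")
}
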