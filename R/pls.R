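# NIPALS PLS1 core: returns weights W, scores T, loadings P, y-loadings q
# on mean-centered data. Components are nested, so coefficient vectors for
# any a <= A can be formed from one decomposition.
.nipalsPls1 <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xc <- sweep(X, 2L, xMean)
  yc <- y - yMean
  if (sum(yc^2) < .Machine$double.eps * n)
    stop("degenerate error: zero-variance response")
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xr <- Xc; yr <- yc
  Aeff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    # nothing left to model (X exhausted or y fitted exactly): later
    # components stay zero and the coefficient vector freezes at Aeff
    if (nw < 1e-12 * max(1, sqrt(sum(Xc^2)) * sqrt(sum(yc^2)))) break
    w <- w / nw
    t <- as.numeric(Xr %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pv <- as.numeric(crossprod(Xr, t)) / tt
    qa <- sum(yr * t) / tt
    Xr <- Xr - tcrossprod(t, pv)
    yr <- yr - t * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    Aeff <- a
  }
  list(W = W, P = P, T = Tm, q = q, xMean = xMean, yMean = yMean,
       Aeff = Aeff)
}

# regression vector in centered space using the first a components
.plsCoef <- function(fit, a) {
  a <- min(a, fit$Aeff)
  if (a == 0L) return(numeric(nrow(fit$W)))
  Wa <- fit$W[, seq_len(a), drop = FALSE]
  Pa <- fit$P[, seq_len(a), drop = FALSE]
  as.numeric(Wa %*% solve(crossprod(Pa, Wa), fit$q[seq_len(a)]))
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares regression with a single response, on
#' mean-centered X and y (no variance scaling; y stays in native units so
#' RMSE is directly interpretable). Score vectors are mutually orthogonal
#' and the training residual is non-increasing in the number of components.
#'
#' @param X numeric matrix [n x p] of preprocessed spectra.
#' @param y numeric response vector, length n, in analyte units.
#' @param A number of components; must not exceed min(n-1, rank of
#'   centered X).
#' @param analyte,units,recipe,wavenumbers optional metadata carried in the
#'   model (the preprocessing recipe the X block was produced with, and the
#'   channel layout it expects).
#' @param cvRmse,cvR2 optional cross-validation curves (stored as-is).
#' @return A \linkS4class{CalibrationModel}.
#' @seealso \code{\link{looCv}}, \code{\link{plsrPredict}}
#' @export
plsrFit <- function(X, y, A, analyte = "", units = "",
                    recipe = PreprocessRecipe("unspecified"),
                    wavenumbers = numeric(), cvRmse = numeric(),
                    cvR2 = numeric()) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("validation error: NA in X or y")
  if (length(y) != nrow(X)) stop("shape error: length(y) != nrow(X)")
  A <- as.integer(A)
  r <- qr(sweep(X, 2L, colMeans(X)))$rank
  if (A > min(nrow(X) - 1L, r))
    stop(sprintf("rank error: A = %d exceeds min(n-1, rank) = %d",
                 A, min(nrow(X) - 1L, r)))
  fit <- .nipalsPls1(X, y, A)
  new("CalibrationModel", analyte = analyte, units = units, recipe = recipe,
      wavenumbers = as.numeric(wavenumbers), A = A,
      xMean = fit$xMean, yMean = fit$yMean, weights = fit$W,
      xLoadings = fit$P, yLoadings = fit$q,
      coefficients = .plsCoef(fit, A),
      cvRmse = cvRmse, cvR2 = cvR2, nTrain = nrow(X),
      yMax = max(y))
}

#' Predict with a PLSR calibration model
#'
#' \code{yhat = yMean + (X - xMean) \%*\% coefficients}.
#'
#' @param m a \linkS4class{CalibrationModel}.
#' @param X numeric matrix (or single row) on the model's channel layout.
#' @return Numeric vector of predictions in the analyte's units.
#' @export
plsrPredict <- function(m, X) {
  stopifnot(is(m, "CalibrationModel"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(m@xMean))
    stop(sprintf("shape error: %d channels supplied, model expects %d",
                 ncol(X), length(m@xMean)))
  as.numeric(m@yMean + sweep(X, 2L, m@xMean) %*% m@coefficients)
}

#' One-sample-out cross-validation of PLS1 over candidate component counts
#'
#' For every left-out sample the model is refit on the remaining n-1
#' samples, re-centering inside the fold, and the held-out sample is
#' predicted with 1..Amax components.
#' \code{RMSE_CV(A) = sqrt(mean((yhat - y)^2))} and
#' \code{R2_CV(A) = 1 - SSE/SST} (which can be negative when predictions
#' are worse than the mean).
#'
#' @param X numeric matrix [n x p], n >= 3.
#' @param y numeric response, length n.
#' @param Amax largest candidate component count, at most n-2.
#' @return List with \code{rmse} and \code{r2} (numeric, one entry per
#'   candidate A) and \code{predictions} (n x Amax matrix of held-out
#'   predictions).
#' @export
looCv <- function(X, y, Amax) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("validation error: need n >= 3 for one-sample-out CV")
  Amax <- as.integer(Amax)
  if (Amax > n - 2L)
    stop("parameter error: Amax must be <= n - 2")
  pred <- matrix(NA_real_, n, Amax)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    if (stats::var(yi) < .Machine$double.eps)
      stop(sprintf("degenerate error: zero-variance response in fold %d", i))
    fit <- .nipalsPls1(Xi, yi, Amax)
    xc <- X[i, ] - fit$xMean
    for (a in seq_len(Amax))
      pred[i, a] <- fit$yMean + sum(xc * .plsCoef(fit, a))
  }
  sse <- colSums((pred - y)^2)
  sst <- sum((y - mean(y))^2)
  list(rmse = sqrt(sse / n), r2 = 1 - sse / sst, predictions = pred)
}

#' Pick the RMSE-optimal number of PLS components
#'
#' \code{Aopt = argmin RMSE_CV(A)}; ties are broken toward the smaller A
#' (parsimony).
#'
#' @param rmseCv numeric vector of cross-validated RMSE per candidate A.
#' @return Integer Aopt.
#' @export
selectComponents <- function(rmseCv) {
  if (!length(rmseCv)) stop("validation error: empty RMSE curve")
  as.integer(which.min(rmseCv))
}
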