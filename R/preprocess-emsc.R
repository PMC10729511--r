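# Legendre polynomial basis P_0..P_degree evaluated on the axis rescaled to
# [-1, 1]; orthogonal polynomials keep the EMSC design well conditioned.
.legendreBasis <- function(w, degree) {
  x <- if (max(w) > min(w)) 2 * (w - min(w)) / (max(w) - min(w)) - 1
       else rep(0, length(w))
  P <- matrix(0, length(w), degree + 1L)
  P[, 1L] <- 1
  if (degree >= 1L) P[, 2L] <- x
  if (degree >= 2L) for (k in 1:(degree - 1L))
    P[, k + 2L] <- ((2 * k + 1) * x * P[, k + 1L] - k * P[, k]) / (k + 1)
  colnames(P) <- paste0("P", 0:degree)
  P
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Decomposes each spectrum by ordinary least squares into a scaled
#' reference spectrum plus a polynomial baseline,
#' \code{raw = b * reference + sum(a_i * P_i) + e}, where the \code{P_i}
#' are Legendre polynomials of order 0..\code{degree} on the axis rescaled
#' to [-1, 1]. The corrected spectrum is \code{(raw - sum(a_i P_i)) / b},
#' which removes additive baselines and multiplicative scatter
#' simultaneously. "Linear and quadratic components" corresponds to
#' \code{degree = 2} (the constant term is always included).
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param reference a \linkS4class{Spectrum} on the same axis, or
#'   \code{"mean"} (default) for the channel-wise mean of \code{s}.
#' @param degree highest polynomial order (>= 0).
#' @return An \linkS4class{EMSCResult}.
#' @export
emsc <- function(s, reference = "mean", degree = 2L) {
  stopifnot(is(s, "SpectraSet"))
  degree <- as.integer(degree)
  if (degree < 0L) stop("parameter error: degree must be >= 0")
  w <- s@wavenumbers
  if (length(w) < degree + 2L)
    stop("parameter error: need at least degree + 2 channels")
  if (identical(reference, "mean")) {
    reference <- Spectrum(w, colMeans(s@intensities))
  }
  stopifnot(is(reference, "Spectrum"))
  if (length(reference@wavenumbers) != length(w) ||
      any(abs(reference@wavenumbers - w) > 1e-9))
    stop("validation error: reference must share the axis of the spectra")
  P <- .legendreBasis(w, degree)
  D <- cbind(ref = reference@intensities, P)
  qrD <- qr(D)
  coefs <- qr.coef(qrD, t(s@intensities))      # (degree+2) x n
  b <- coefs[1L, ]
  a <- coefs[-1L, , drop = FALSE]
  if (any(abs(b) < 1e-10)) {
    bad <- which(abs(b) < 1e-10)[1L]
    stop(sprintf("degenerate-fit error: |b| < 1e-10 for spectrum %d", bad))
  }
  corrected <- (s@intensities - t(P %*% a)) / b
  out <- SpectraSet(w, corrected, s@times, labels = s@labels,
                    provenance = c(s@provenance,
                                   sprintf("emsc(degree=%d)", degree)))
  new("EMSCResult", corrected = out, multiplicative = unname(b),
      additive = t(unname(a)), reference = reference)
}
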