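# Savitzky-Golay smoothing / derivatives with one-sided truncated-window
# refits at the edges (no reflection padding), derivative reported per
# (cm^-1)^deriv with respect to increasing wavenumber.

.savgol1 <- function(ya, window, polyorder, deriv, dx) {
  n <- length(ya)
  h <- (window - 1L) %/% 2L
  # interior convolution coefficients: row `deriv` of the pseudoinverse of
  # the local Vandermonde design, times deriv!
  z <- seq(-h, h)
  A <- outer(z, 0:polyorder, `^`)
  Pinv <- solve(crossprod(A), t(A))
  cvec <- Pinv[deriv + 1L, ] * factorial(deriv)
  out <- numeric(n)
  if (n >= window) {
    E <- stats::embed(ya, window)        # rows: y[i+h..i-h] reversed order
    interior <- as.numeric(E %*% rev(cvec))
    out[(h + 1L):(n - h)] <- interior
  }
  edge <- c(seq_len(min(h, n)), if (n > h) seq(max(h + 1L, n - h + 1L), n))
  for (i in unique(edge)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    zz <- seq(lo, hi) - i
    Ai <- outer(zz, 0:polyorder, `^`)
    b <- solve(crossprod(Ai), crossprod(Ai, ya[lo:hi]))
    out[i] <- b[deriv + 1L] * factorial(deriv)
  }
  out / dx^deriv
}

.checkSgParams <- function(window, polyorder, deriv, n) {
  if (window %% 2L == 0L)
    stop("parameter error: window must be odd")
  if (window <= polyorder)
    stop("parameter error: window must exceed polyorder")
  if (deriv > polyorder)
    stop("parameter error: deriv must not exceed polyorder")
  if (window > n)
    stop("parameter error: window exceeds the number of channels")
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering. Interior points use the closed
#' convolution weights; the first and last \code{(window-1)/2} points are
#' refit on the truncated one-sided window rather than padded. Derivatives
#' are reported per (cm^-1)^deriv with respect to increasing wavenumber,
#' assuming a uniform grid (the index-space derivative divided by the grid
#' spacing to the power \code{deriv}).
#'
#' @param s a \linkS4class{Spectrum} or \linkS4class{SpectraSet}.
#' @param window odd window length in channels (e.g. 9).
#' @param polyorder polynomial order (e.g. 2); must be < window.
#' @param deriv derivative order (0 = smoothing); must be <= polyorder.
#' @return Object of the same class as \code{s}.
#' @export
setGeneric("savitzkyGolay", function(s, window, polyorder, deriv = 0L)
  standardGeneric("savitzkyGolay"))

#' @rdname savitzkyGolay
#' @export
setMethod("savitzkyGolay", "Spectrum", function(s, window, polyorder,
                                                deriv = 0L) {
  .checkSgParams(window, polyorder, deriv, nChannels(s))
  wa <- rev(s@wavenumbers)
  dx <- mean(diff(wa))
  y <- .savgol1(rev(s@intensities), window, polyorder, deriv, dx)
  Spectrum(s@wavenumbers, rev(y))
})

#' @rdname savitzkyGolay
#' @export
setMethod("savitzkyGolay", "SpectraSet", function(s, window, polyorder,
                                                  deriv = 0L) {
  .checkSgParams(window, polyorder, deriv, nChannels(s))
  wa <- rev(s@wavenumbers)
  dx <- mean(diff(wa))
  out <- t(apply(s@intensities, 1L, function(row)
    rev(.savgol1(rev(row), window, polyorder, deriv, dx))))
  SpectraSet(s@wavenumbers, out, s@times, labels = s@labels,
             provenance = c(s@provenance,
                            sprintf("savgol(%d,%d,%d)", window, polyorder,
                                    deriv)))
})
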