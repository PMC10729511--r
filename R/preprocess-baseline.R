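# Lower convex hull of (x, y) with x strictly ascending: Andrew monotone
# chain, returning vertex indices. Pop while the middle point is on or above
# the chord (cross product <= 0).
.lowerHullIdx <- function(x, y) {
  n <- length(x)
  h <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      k <- h[m - 1L]; j <- h[m]
      cr <- (x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k])
      if (cr <= 0) m <- m - 1L else break
    }
    m <- m + 1L
    h[m] <- i
  }
  h[seq_len(m)]
}

.rubberband1 <- function(w, y) {
  # work in ascending wavenumber order
  xa <- rev(w); ya <- rev(y)
  hull <- .lowerHullIdx(xa, ya)
  base <- stats::approx(xa[hull], ya[hull], xout = xa)$y
  rev(base)  # back to descending storage order
}

#' Rubber-band (convex hull) baseline correction
#'
#' Estimates the additive background of a spectrum as the lower convex hull
#' of its (wavenumber, intensity) points, linearly interpolated between hull
#' vertices, and subtracts it. The corrected spectrum is zero at the first
#' and last channel and at every hull vertex, non-negative everywhere, and
#' the operation is idempotent.
#'
#' @param s a \linkS4class{Spectrum} or \linkS4class{SpectraSet} (corrected
#'   per spectrum).
#' @return For a \code{Spectrum}: list with \code{corrected} and
#'   \code{baseline} (both \code{Spectrum}). For a \code{SpectraSet}: list
#'   with \code{corrected} (a \code{SpectraSet}) and \code{baseline} (a
#'   matrix of per-spectrum baselines).
#' @export
setGeneric("rubberbandBaseline",
           function(s) standardGeneric("rubberbandBaseline"))

#' @rdname rubberbandBaseline
#' @export
setMethod("rubberbandBaseline", "Spectrum", function(s) {
  if (nChannels(s) < 3)
    stop("validation error: rubber-band baseline needs >= 3 channels")
  base <- .rubberband1(s@wavenumbers, s@intensities)
  list(corrected = Spectrum(s@wavenumbers, s@intensities - base),
       baseline = Spectrum(s@wavenumbers, base))
})

#' @rdname rubberbandBaseline
#' @export
setMethod("rubberbandBaseline", "SpectraSet", function(s) {
  if (nChannels(s) < 3)
    stop("validation error: rubber-band baseline needs >= 3 channels")
  base <- t(apply(s@intensities, 1L,
                  function(row) .rubberband1(s@wavenumbers, row)))
  corr <- SpectraSet(s@wavenumbers, s@intensities - base, s@times,
                     labels = s@labels,
                     provenance = c(s@provenance, "rubberband"))
  list(corrected = corr, baseline = base)
})
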