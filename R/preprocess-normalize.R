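.peaknorm1 <- function(w, y, anchor, halfwidth) {
  win <- which(abs(w - anchor) <= halfwidth)
  if (!length(win))
    stop(sprintf("validation error: window [%g +/- %g] does not overlap the axis",
                 anchor, halfwidth))
  m <- max(y[win])
  if (m <= 0)
    stop(sprintf(paste0("normalization error: window maximum at %g cm-1 is ",
                        "<= 0 (baseline not removed or dead channel?)"),
                 anchor))
  y / m
}

#' Anchor-peak normalization
#'
#' Divides each spectrum by the maximum intensity within a window around an
#' anchor band, so the located peak has value 1. Typical anchors for online
#' broth spectra through a glass flow cell are the glass band at 800 cm^-1
#' (internal standard) and the water band at 3200 cm^-1 (external standard).
#' The windowed maximum (default halfwidth 16 cm^-1, about two resolution
#' elements at 8 cm^-1 spectral resolution) is robust to grid offsets
#' between instruments. Scale-invariant and idempotent.
#'
#' @param s a \linkS4class{Spectrum} or \linkS4class{SpectraSet}
#'   (normalized per spectrum).
#' @param anchor anchor position in cm^-1.
#' @param halfwidth window halfwidth in cm^-1 (default 16).
#' @return Object of the same class as \code{s}.
#' @export
setGeneric("peakNormalize", function(s, anchor, halfwidth = 16)
  standardGeneric("peakNormalize"))

#' @rdname peakNormalize
#' @export
setMethod("peakNormalize", "Spectrum", function(s, anchor, halfwidth = 16) {
  Spectrum(s@wavenumbers,
           .peaknorm1(s@wavenumbers, s@intensities, anchor, halfwidth))
})

#' @rdname peakNormalize
#' @export
setMethod("peakNormalize", "SpectraSet", function(s, anchor, halfwidth = 16) {
  out <- t(apply(s@intensities, 1L, function(row)
    .peaknorm1(s@wavenumbers, row, anchor, halfwidth)))
  SpectraSet(s@wavenumbers, out, s@times, labels = s@labels,
             provenance = c(s@provenance,
                            sprintf("peak_normalize(%g)", anchor)))
})
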