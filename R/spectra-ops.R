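#' Resample a spectra set onto a new wavenumber grid
#'
#' Channel-wise linear interpolation. The target grid must lie within the
#' span of the source axis (no extrapolation); values at grid points shared
#' with the source axis are preserved exactly.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param grid numeric target axis in cm^-1 (any monotonic order; stored
#'   descending).
#' @return A \linkS4class{SpectraSet} on the new grid.
#' @export
resampleToGrid <- function(s, grid) {
  stopifnot(is(s, "SpectraSet"))
  grid <- as.numeric(grid)
  w <- s@wavenumbers
  if (min(grid) < min(w) || max(grid) > max(w))
    stop(sprintf("range error: grid [%g, %g] extends past source axis [%g, %g]",
                 min(grid), max(grid), min(w), max(w)))
  gs <- sort(grid, decreasing = TRUE)
  # approx needs ascending x
  wa <- rev(w)
  out <- t(apply(s@intensities, 1L, function(row)
    stats::approx(wa, rev(row), xout = rev(gs))$y))
  out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  SpectraSet(wavenumbers = gs, intensities = out, times = s@times,
             labels = s@labels,
             provenance = c(s@provenance,
                            sprintf("resample(%d channels)", length(gs))))
}

#' Truncate spectra to a set of wavenumber regions
#'
#' Removes all channels outside the given closed intervals (bounds inclusive
#' on both ends). Channel order is preserved high-to-low across regions.
#' Idempotent for a fixed \linkS4class{RegionSet}.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param r a \linkS4class{RegionSet}, e.g.
#'   \code{RegionSet(c(3050, 2500), c(1800, 650))}.
#' @return A truncated \linkS4class{SpectraSet}.
#' @export
truncateRegions <- function(s, r) {
  stopifnot(is(s, "SpectraSet"), is(r, "RegionSet"))
  w <- s@wavenumbers
  reg <- r@regions
  keep <- rep(FALSE, length(w))
  for (i in seq_len(nrow(reg))) {
    inreg <- w <= reg[i, "high"] & w >= reg[i, "low"]
    if (!any(inreg))
      stop(sprintf("validation error: region [%g, %g] contains no channels",
                   reg[i, "high"], reg[i, "low"]))
    keep <- keep | inreg
  }
  SpectraSet(wavenumbers = w[keep],
             intensities = s@intensities[, keep, drop = FALSE],
             times = s@times, labels = s@labels,
             provenance = c(s@provenance,
                            sprintf("truncate(%s)",
                                    paste(sprintf("%g-%g", reg[, "high"],
                                                  reg[, "low"]),
                                          collapse = ";"))))
}

#' Align spectra to reference sampling timepoints
#'
#' Pairs the online spectral time series (X-block) with the offline
#' reference measurements (y-block). Each reference timepoint is matched to
#' either the single nearest spectrum (\code{policy = "nearest"}, ties
#' broken toward the earlier spectrum) or the unweighted mean of all spectra
#' acquired within \code{windowH} hours (\code{policy = "mean"}, the
#' default: a single 1024-scan acquisition takes about 15 min, so averaging
#' neighbouring spectra suppresses acquisition noise).
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param ref a \linkS4class{ReferenceTable}.
#' @param windowH half-width of the matching window in hours (default 0.5).
#' @param policy \code{"mean"} (default) or \code{"nearest"}.
#' @return A list with elements \code{X} (matrix, one row per reference
#'   timepoint), \code{y} (the reference value matrix, analytes in columns),
#'   \code{timepoints}, \code{matchedTimes} (list of the acquisition times
#'   used per timepoint), and \code{wavenumbers}.
#' @export
alignToReference <- function(s, ref, windowH = 0.5,
                             policy = c("mean", "nearest")) {
  stopifnot(is(s, "SpectraSet"), is(ref, "ReferenceTable"))
  policy <- match.arg(policy)
  tp <- ref@timepoints
  ts <- s@times
  sel <- lapply(tp, function(t0) which(abs(ts - t0) <= windowH))
  uncovered <- tp[vapply(sel, length, 1L) == 0L]
  if (length(uncovered))
    stop("alignment error: no spectrum within ", windowH,
         " h of timepoint(s): ", paste(uncovered, collapse = ", "))
  X <- matrix(0, length(tp), nChannels(s))
  matched <- vector("list", length(tp))
  for (i in seq_along(tp)) {
    idx <- sel[[i]]
    if (policy == "nearest") {
      idx <- idx[which.min(abs(ts[idx] - tp[i]))]
      X[i, ] <- s@intensities[idx, ]
    } else {
      X[i, ] <- colMeans(s@intensities[idx, , drop = FALSE])
    }
    matched[[i]] <- ts[idx]
  }
  list(X = X, y = ref@values, timepoints = tp, matchedTimes = matched,
       wavenumbers = s@wavenumbers)
}
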