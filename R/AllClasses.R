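#' @import methods
NULL

.validSpectrum <- function(object) {
  msg <- character()
  w <- object@wavenumbers
  y <- object@intensities
  if (length(w) != length(y))
    msg <- c(msg, "wavenumbers and intensities must have equal length")
  if (anyNA(w) || anyNA(y))
    msg <- c(msg, "NA values are not allowed in a Spectrum")
  if (length(w) >= 2 && any(diff(w) >= 0))
    msg <- c(msg, "wavenumber axis must be strictly monotonic descending")
  if (length(msg)) msg else TRUE
}

#' Single vibrational spectrum
#'
#' A single spectrum on a strictly monotonic wavenumber axis, stored in
#' descending wavenumber order (the plotting convention for Raman and
#' infrared spectra). Intensities are in arbitrary instrument units.
#'
#' @slot wavenumbers numeric, cm^-1, strictly descending.
#' @slot intensities numeric, same length as \code{wavenumbers}.
#' @export
setClass("Spectrum",
         representation(wavenumbers = "numeric", intensities = "numeric"),
         validity = .validSpectrum)

#' Create a Spectrum
#'
#' Values supplied in ascending wavenumber order are flipped to the
#' canonical descending storage order.
#'
#' @param wavenumbers numeric axis in cm^-1, strictly monotonic.
#' @param intensities numeric intensities, same length.
#' @return A \linkS4class{Spectrum}.
#' @export
#' @examples
#' s <- Spectrum(c(1000, 900, 800), c(1, 2, 1))
Spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) >= 2 && all(diff(wavenumbers) > 0)) {
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
  }
  new("Spectrum", wavenumbers = wavenumbers, intensities = intensities)
}

.validSpectraSet <- function(object) {
  msg <- character()
  w <- object@wavenumbers
  x <- object@intensities
  t <- object@times
  if (!is.matrix(x)) msg <- c(msg, "intensities must be a matrix")
  else {
    if (ncol(x) != length(w))
      msg <- c(msg, "intensity columns must match the wavenumber axis")
    if (nrow(x) != length(t))
      msg <- c(msg, "intensity rows must correspond 1:1 to acquisition times")
  }
  if (anyNA(w) || anyNA(x)) msg <- c(msg, "NA values are not allowed")
  if (length(w) >= 2 && any(diff(w) >= 0))
    msg <- c(msg, "wavenumber axis must be strictly monotonic descending")
  if (length(t) >= 2 && any(diff(t) < 0))
    msg <- c(msg, "acquisition times must be non-decreasing")
  if (length(object@labels) && length(object@labels) != length(t))
    msg <- c(msg, "labels must be empty or one per spectrum")
  if (length(msg)) msg else TRUE
}

#' Time-resolved set of spectra sharing one axis
#'
#' The X-block of a calibration: one row per acquired spectrum, one column
#' per wavenumber channel, plus acquisition times in hours from inoculation
#' and free-form per-spectrum labels (e.g. a modality tag such as
#' \code{"online-raman"}).
#'
#' @slot wavenumbers shared axis, cm^-1, strictly descending.
#' @slot intensities numeric matrix [n_spectra x n_channels].
#' @slot times numeric, acquisition time in hours, non-decreasing.
#' @slot labels character, per-spectrum metadata (may be empty).
#' @slot provenance character, ordered record of processing steps applied.
#' @export
setClass("SpectraSet",
         representation(wavenumbers = "numeric", intensities = "matrix",
                        times = "numeric", labels = "character",
                        provenance = "character"),
         validity = .validSpectraSet)

#' Create a SpectraSet
#'
#' @param wavenumbers shared axis in cm^-1 (ascending input is flipped to
#'   the canonical descending order, with intensity columns reversed).
#' @param intensities numeric matrix, one row per spectrum.
#' @param times acquisition times in hours, one per row, non-decreasing.
#' @param labels optional per-spectrum character labels.
#' @param provenance optional character record of processing applied.
#' @return A \linkS4class{SpectraSet}.
#' @export
SpectraSet <- function(wavenumbers, intensities, times,
                       labels = character(), provenance = character()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- NULL
  if (length(wavenumbers) >= 2 && all(diff(wavenumbers) > 0)) {
    wavenumbers <- rev(wavenumbers)
    intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
  }
  new("SpectraSet", wavenumbers = wavenumbers, intensities = intensities,
      times = as.numeric(times), labels = as.character(labels),
      provenance = as.character(provenance))
}

.refUnits <- c("g/L", "mg/L", "%w/w", "permille_w/w")

.validReferenceTable <- function(object) {
  msg <- character()
  v <- object@values
  tp <- object@timepoints
  u <- object@units
  if (!is.matrix(v)) msg <- c(msg, "values must be a matrix")
  else {
    if (nrow(v) != length(tp))
      msg <- c(msg, "one row of values per timepoint required")
    if (ncol(v) != length(u))
      msg <- c(msg, "one declared unit per analyte required")
    if (is.null(colnames(v)) || any(!nzchar(colnames(v))))
      msg <- c(msg, "analyte names (column names of values) are required")
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, "reference values must be >= 0 where present")
  }
  if (length(tp) >= 2 && any(diff(tp) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (!all(u %in% .refUnits))
    msg <- c(msg, sprintf("units must be one of: %s",
                          paste(.refUnits, collapse = ", ")))
  if (length(msg)) msg else TRUE
}

#' Offline reference measurements per sampling timepoint
#'
#' The y-block of a calibration: analyte values measured offline (assay kit,
#' HPLC, gravimetry, GC) at discrete sampling timepoints. Missing values are
#' allowed and are dropped per-analyte when models are fitted.
#'
#' @slot timepoints numeric hours, strictly increasing.
#' @slot values numeric matrix [n_timepoints x n_analytes], NA allowed,
#'   non-negative where present; column names are the analyte names.
#' @slot units named character, one of \code{g/L}, \code{mg/L}, \code{\%w/w},
#'   \code{permille_w/w}, per analyte.
#' @export
setClass("ReferenceTable",
         representation(timepoints = "numeric", values = "matrix",
                        units = "character"),
         validity = .validReferenceTable)

#' Create a ReferenceTable
#'
#' @param timepoints sampling times in hours, strictly increasing.
#' @param values numeric matrix with analyte column names; NA allowed.
#' @param units character vector of units, one per analyte column.
#' @return A \linkS4class{ReferenceTable}.
#' @export
ReferenceTable <- function(timepoints, values, units) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  units <- as.character(units)
  names(units) <- colnames(values)
  new("ReferenceTable", timepoints = as.numeric(timepoints),
      values = values, units = units)
}

.validRegionSet <- function(object) {
  msg <- character()
  r <- object@regions
  if (!is.matrix(r) || ncol(r) != 2)
    return("regions must be a two-column (high, low) matrix")
  if (any(r[, 1] <= r[, 2]))
    msg <- c(msg, "each region must have high > low")
  if (nrow(r) >= 2) {
    o <- order(r[, 1], decreasing = TRUE)
    rs <- r[o, , drop = FALSE]
    for (i in seq_len(nrow(rs) - 1)) {
      if (rs[i + 1, 1] >= rs[i, 2])
        msg <- c(msg, "regions must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
}

#' Set of closed wavenumber intervals
#'
#' Used to truncate spectra to informative regions, e.g. the C-H stretch
#' (3050-2500 cm^-1) and fingerprint (1800-650 cm^-1) windows. Bounds are
#' inclusive on both ends.
#'
#' @slot regions numeric matrix with columns \code{high}, \code{low} (cm^-1).
#' @export
setClass("RegionSet", representation(regions = "matrix"),
         validity = .validRegionSet)

#' Create a RegionSet
#'
#' @param ... each argument a length-2 numeric \code{c(high, low)} interval
#'   in cm^-1, or a single two-column matrix.
#' @return A \linkS4class{RegionSet}.
#' @export
#' @examples
#' RegionSet(c(3050, 2500), c(1800, 650))
RegionSet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.matrix(args[[1L]])) {
    r <- args[[1L]]
  } else {
    r <- do.call(rbind, lapply(args, function(x) as.numeric(x)[1:2]))
  }
  colnames(r) <- c("high", "low")
  new("RegionSet", regions = r)
}

.validRecipe <- function(object) {
  kinds <- c("rubberband", "savgol", "peak_normalize", "emsc", "truncate")
  msg <- character()
  for (i in seq_along(object@steps)) {
    st <- object@steps[[i]]
    if (!is.list(st) || is.null(st$kind) || !(st$kind %in% kinds)) {
      msg <- c(msg, sprintf("step %d: kind must be one of %s", i,
                            paste(kinds, collapse = ", ")))
      next
    }
    need <- switch(st$kind,
                   rubberband = character(),
                   savgol = c("window", "polyorder", "deriv"),
                   peak_normalize = c("anchor", "halfwidth"),
                   emsc = "degree",
                   truncate = "regions")
    miss <- setdiff(need, names(st))
    if (length(miss))
      msg <- c(msg, sprintf("step %d (%s): missing parameter(s) %s", i,
                            st$kind, paste(miss, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

#' Ordered, parameterized preprocessing recipe
#'
#' A named sequence of pretreatment steps (\code{rubberband}, \code{savgol},
#' \code{peak_normalize}, \code{emsc}, \code{truncate}) applied strictly in
#' order by \code{\link{applyRecipe}}. Serializes deterministically to a
#' plain-text YAML config via \code{\link{writeRecipe}}.
#'
#' @slot name character identifier.
#' @slot steps list of step descriptors; each a list with element
#'   \code{kind} and the parameters of that step kind.
#' @export
setClass("PreprocessRecipe",
         representation(name = "character", steps = "list"),
         validity = .validRecipe)

#' Create a PreprocessRecipe
#'
#' @param name recipe identifier.
#' @param steps list of step descriptors (see class docs). An empty list is
#'   the identity recipe.
#' @return A \linkS4class{PreprocessRecipe}.
#' @seealso \code{\link{builtinRecipe}} for the named recipes shipped with
#'   the package.
#' @export
PreprocessRecipe <- function(name, steps = list()) {
  new("PreprocessRecipe", name = name, steps = steps)
}

#' Result of extended multiplicative signal correction
#'
#' @slot corrected the corrected \linkS4class{SpectraSet}:
#'   \code{(raw - sum(a_i P_i)) / b} channel-wise.
#' @slot multiplicative numeric, the scatter factor b per spectrum.
#' @slot additive numeric matrix [n_spectra x (degree+1)] of polynomial
#'   coefficients a_0..a_degree in the Legendre basis on [-1, 1].
#' @slot reference the \linkS4class{Spectrum} used as reference.
#' @export
setClass("EMSCResult",
         representation(corrected = "SpectraSet", multiplicative = "numeric",
                        additive = "matrix", reference = "Spectrum"))

#' Fitted PLSR calibration model
#'
#' PLS1 (single-response) partial least squares regression fitted by NIPALS
#' on mean-centered data, carrying its preprocessing recipe, the
#' cross-validation curves used to pick the number of components (Aopt),
#' and everything needed to predict new spectra.
#'
#' @slot analyte analyte name.
#' @slot units analyte units.
#' @slot recipe the \linkS4class{PreprocessRecipe} the model expects.
#' @slot wavenumbers the channel layout (post-recipe axis) the model expects.
#' @slot A integer, number of PLS components in use (Aopt).
#' @slot xMean,yMean centering vector / scalar.
#' @slot weights,xLoadings numeric matrices [p x A].
#' @slot yLoadings numeric length A.
#' @slot coefficients regression vector in centered space, length p.
#' @slot cvRmse,cvR2 cross-validation RMSE and R^2 per candidate A
#'   (empty if the model was fitted without CV).
#' @slot nTrain number of training samples.
#' @slot yMax maximum training reference value (for RMSE as percent-of-max).
#' @export
setClass("CalibrationModel",
         representation(analyte = "character", units = "character",
                        recipe = "PreprocessRecipe", wavenumbers = "numeric",
                        A = "integer", xMean = "numeric", yMean = "numeric",
                        weights = "matrix", xLoadings = "matrix",
                        yLoadings = "numeric", coefficients = "numeric",
                        cvRmse = "numeric", cvR2 = "numeric",
                        nTrain = "integer", yMax = "numeric"))

#' Model-quality report
#'
#' @slot r2 coefficient of determination, 1 - SSE/SST (can be negative).
#' @slot rmse root-mean-square error in analyte units.
#' @slot rmsePctOfMax 100 * rmse / max(reference values).
#' @slot n number of samples.
#' @slot kind \code{"cv"} or \code{"test"}.
#' @export
setClass("ValidationReport",
         representation(r2 = "numeric", rmse = "numeric",
                        rmsePctOfMax = "numeric", n = "integer",
                        kind = "character"))
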