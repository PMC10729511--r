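#' @name accessors
#' @title Accessors for RamanPAT objects
#' @description Slot accessors for the core S4 containers. Use these rather
#'   than \code{@} access.
#' @param object an object of the documented classes.
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("acquisitionTimes",
           function(object) standardGeneric("acquisitionTimes"))
#' @rdname accessors
#' @export
setGeneric("spectraLabels", function(object) standardGeneric("spectraLabels"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("nSpectra", function(object) standardGeneric("nSpectra"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("analytes", function(object) standardGeneric("analytes"))
#' @rdname accessors
#' @export
setGeneric("timepoints", function(object) standardGeneric("timepoints"))
#' @rdname accessors
#' @export
setGeneric("analyteUnits", function(object) standardGeneric("analyteUnits"))
#' @rdname accessors
#' @export
setGeneric("referenceValues",
           function(object) standardGeneric("referenceValues"))
#' @rdname accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("recipeSteps", function(object) standardGeneric("recipeSteps"))
#' @rdname accessors
#' @export
setGeneric("recipeName", function(object) standardGeneric("recipeName"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("cvCurves", function(object) standardGeneric("cvCurves"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(object) object@wavenumbers)
#' @rdname accessors
#' @export
setMethod("wavenumbers", "SpectraSet", function(object) object@wavenumbers)
#' @rdname accessors
#' @export
setMethod("wavenumbers", "CalibrationModel",
          function(object) object@wavenumbers)
#' @rdname accessors
#' @export
setMethod("intensities", "Spectrum", function(object) object@intensities)
#' @rdname accessors
#' @export
setMethod("intensities", "SpectraSet", function(object) object@intensities)
#' @rdname accessors
#' @export
setMethod("acquisitionTimes", "SpectraSet", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("spectraLabels", "SpectraSet", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("provenance", "SpectraSet", function(object) object@provenance)
#' @rdname accessors
#' @export
setMethod("nSpectra", "SpectraSet", function(object) nrow(object@intensities))
#' @rdname accessors
#' @export
setMethod("nChannels", "SpectraSet", function(object) ncol(object@intensities))
#' @rdname accessors
#' @export
setMethod("nChannels", "Spectrum", function(object) length(object@wavenumbers))
#' @rdname accessors
#' @export
setMethod("analytes", "ReferenceTable",
          function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("timepoints", "ReferenceTable", function(object) object@timepoints)
#' @rdname accessors
#' @export
setMethod("analyteUnits", "ReferenceTable", function(object) object@units)
#' @rdname accessors
#' @export
setMethod("analyteUnits", "CalibrationModel", function(object) object@units)
#' @rdname accessors
#' @export
setMethod("referenceValues", "ReferenceTable", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("regions", "RegionSet", function(object) object@regions)
#' @rdname accessors
#' @export
setMethod("recipeSteps", "PreprocessRecipe", function(object) object@steps)
#' @rdname accessors
#' @export
setMethod("recipeName", "PreprocessRecipe", function(object) object@name)
#' @rdname accessors
#' @export
setMethod("nComponents", "CalibrationModel", function(object) object@A)
#' @rdname accessors
#' @export
setMethod("cvCurves", "CalibrationModel",
          function(object) list(rmse = object@cvRmse, r2 = object@cvR2))

setMethod("show", "Spectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("Spectrum: %d channels, %.6g..%.6g cm-1\n",
              length(w), max(w), min(w)))
})

setMethod("show", "SpectraSet", function(object) {
  w <- object@wavenumbers
  cat(sprintf("SpectraSet: %d spectra x %d channels\n",
              nrow(object@intensities), ncol(object@intensities)))
  if (length(w))
    cat(sprintf("  axis: %.6g..%.6g cm-1 (descending)\n", max(w), min(w)))
  if (length(object@times))
    cat(sprintf("  times: %.3g..%.3g h\n",
                min(object@times), max(object@times)))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d timepoints x %d analytes\n",
              length(object@timepoints), ncol(object@values)))
  for (a in colnames(object@values))
    cat(sprintf("  %s [%s]: %d values\n", a, object@units[[a]],
                sum(!is.na(object@values[, a]))))
})

setMethod("show", "RegionSet", function(object) {
  r <- object@regions
  cat("RegionSet:",
      paste(sprintf("[%g, %g]", r[, "high"], r[, "low"]), collapse = " "),
      "cm-1\n")
})

setMethod("show", "PreprocessRecipe", function(object) {
  cat(sprintf("PreprocessRecipe '%s' (%d steps)\n",
              object@name, length(object@steps)))
  for (i in seq_along(object@steps)) {
    st <- object@steps[[i]]
    pars <- st[setdiff(names(st), "kind")]
    cat(sprintf("  %d. %s(%s)\n", i, st$kind,
                paste(names(pars), vapply(pars, function(p)
                  paste(format(unlist(p)), collapse = ","), ""),
                  sep = "=", collapse = ", ")))
  }
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: %s [%s], A = %d, n = %d\n",
              object@analyte, object@units, object@A, object@nTrain))
  if (length(object@cvRmse))
    cat(sprintf("  RMSE_CV(Aopt) = %.4g, R2_CV(Aopt) = %.4g\n",
                object@cvRmse[object@A], object@cvR2[object@A]))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport (%s): R2 = %.4g, RMSE = %.4g (%.1f%%), n = %d\n",
              object@kind, object@r2, object@rmse,
              object@rmsePctOfMax, object@n))
})
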