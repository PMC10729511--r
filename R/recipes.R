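.builtinRecipes <- function() {
  onlineRegions <- list(c(3050, 2500), c(1800, 650))
  list(
    online_glass = PreprocessRecipe("online_glass", list(
      list(kind = "rubberband"),
      list(kind = "savgol", window = 9L, polyorder = 2L, deriv = 0L),
      list(kind = "peak_normalize", anchor = 800, halfwidth = 16),
      list(kind = "truncate", regions = onlineRegions))),
    online_water = PreprocessRecipe("online_water", list(
      list(kind = "rubberband"),
      list(kind = "savgol", window = 9L, polyorder = 2L, deriv = 0L),
      list(kind = "peak_normalize", anchor = 3200, halfwidth = 16),
      list(kind = "truncate", regions = onlineRegions))),
    online_emsc_d4 = PreprocessRecipe("online_emsc_d4", list(
      list(kind = "rubberband"),
      list(kind = "savgol", window = 9L, polyorder = 2L, deriv = 0L),
      list(kind = "truncate", regions = onlineRegions),
      list(kind = "emsc", degree = 4L))),
    online_emsc_d6 = PreprocessRecipe("online_emsc_d6", list(
      list(kind = "rubberband"),
      list(kind = "savgol", window = 9L, polyorder = 2L, deriv = 0L),
      list(kind = "truncate", regions = onlineRegions),
      list(kind = "emsc", degree = 6L))),
    hts_ftir = PreprocessRecipe("hts_ftir", list(
      list(kind = "savgol", window = 15L, polyorder = 2L, deriv = 2L),
      list(kind = "truncate", regions = list(c(3050, 2800), c(1800, 900))),
      list(kind = "emsc", degree = 2L))),
    hts_raman = PreprocessRecipe("hts_raman", list(
      list(kind = "savgol", window = 9L, polyorder = 2L, deriv = 0L),
      list(kind = "truncate", regions = onlineRegions),
      list(kind = "rubberband"),
      list(kind = "emsc", degree = 2L))))
}

#' Built-in preprocessing recipes
#'
#' The named pretreatment sequences for the supported modalities:
#' \describe{
#'   \item{online_glass}{rubber band, SG(9,2,0), peak normalization to the
#'     800 cm^-1 glass band, truncation to 3050-2500 and 1800-650 cm^-1.}
#'   \item{online_water}{as above but normalized to the 3200 cm^-1 water
#'     band.}
#'   \item{online_emsc_d4 / online_emsc_d6}{rubber band, SG(9,2,0),
#'     truncation, then EMSC with polynomial terms up to order 4 / 6.}
#'   \item{hts_ftir}{SG second derivative (15,2,2), truncation to 3050-2800
#'     and 1800-900 cm^-1, EMSC with linear and quadratic components.}
#'   \item{hts_raman}{SG(9,2,0), truncation, rubber band, EMSC degree 2.}
#' }
#'
#' @param name recipe name; omit to get the names of all built-ins.
#' @return A \linkS4class{PreprocessRecipe}, or a character vector of names
#'   if \code{name} is missing.
#' @export
builtinRecipe <- function(name) {
  all <- .builtinRecipes()
  if (missing(name)) return(names(all))
  if (!name %in% names(all))
    stop("unknown recipe '", name, "'; valid names: ",
         paste(names(all), collapse = ", "))
  all[[name]]
}

#' Apply a preprocessing recipe to a spectra set
#'
#' Steps are applied strictly in their listed order; each step appends a
#' provenance record to the output. Errors raised by a step are annotated
#' with the step index. An empty recipe is the identity.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param r a \linkS4class{PreprocessRecipe} or a built-in recipe name.
#' @return The preprocessed \linkS4class{SpectraSet}.
#' @export
applyRecipe <- function(s, r) {
  stopifnot(is(s, "SpectraSet"))
  if (is.character(r)) r <- builtinRecipe(r)
  stopifnot(is(r, "PreprocessRecipe"))
  for (i in seq_along(r@steps)) {
    st <- r@steps[[i]]
    s <- tryCatch(switch(st$kind,
      rubberband = rubberbandBaseline(s)$corrected,
      savgol = savitzkyGolay(s, st$window, st$polyorder, st$deriv),
      peak_normalize = peakNormalize(s, st$anchor,
                                     st$halfwidth %||% 16),
      emsc = emsc(s, st$reference %||% "mean", st$degree)@corrected,
      truncate = truncateRegions(s, do.call(RegionSet, st$regions)),
      stop("unknown step kind: ", st$kind)),
      error = function(e)
        stop(sprintf("recipe '%s' step %d (%s): %s", r@name, i, st$kind,
                     conditionMessage(e)), call. = FALSE))
  }
  s
}

#' Serialize a recipe to a plain-text (YAML) config
#'
#' @param r a \linkS4class{PreprocessRecipe}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecipe <- function(r, path) {
  stopifnot(is(r, "PreprocessRecipe"))
  yaml::write_yaml(list(name = r@name, steps = r@steps), path)
  invisible(path)
}

#' Read a recipe from a plain-text (YAML) config
#'
#' @param path path to a config written by \code{\link{writeRecipe}}.
#' @return A \linkS4class{PreprocessRecipe}.
#' @export
readRecipe <- function(path) {
  cfg <- yaml::read_yaml(path)
  steps <- lapply(cfg$steps, function(st) {
    for (f in c("window", "polyorder", "deriv", "degree"))
      if (!is.null(st[[f]])) st[[f]] <- as.integer(st[[f]])
    if (!is.null(st$regions))
      st$regions <- lapply(st$regions, as.numeric)
    st
  })
  PreprocessRecipe(cfg$name, steps)
}
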