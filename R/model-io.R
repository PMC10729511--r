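.md5Object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Serialize a calibration model to a single JSON document
#'
#' The document carries the recipe, centering vectors, weights/loadings,
#' regression coefficients, CV curves and (optionally) a provenance hash of
#' the training inputs, so a model can be reloaded and applied elsewhere.
#'
#' @param m a \linkS4class{CalibrationModel}.
#' @param path output path.
#' @param trainingHash optional md5 hash of the training X/y (as computed
#'   by the calibration pipeline).
#' @return \code{path}, invisibly.
#' @export
writeCalibrationModel <- function(m, path, trainingHash = NULL) {
  stopifnot(is(m, "CalibrationModel"))
  doc <- list(
    format = "RamanPAT-calibration-model",
    analyte = m@analyte, units = m@units,
    recipe = list(name = m@recipe@name, steps = m@recipe@steps),
    wavenumbers = m@wavenumbers,
    A = m@A, x_mean = m@xMean, y_mean = m@yMean,
    weights = m@weights, x_loadings = m@xLoadings,
    y_loadings = m@yLoadings, coefficients = m@coefficients,
    cv_rmse = m@cvRmse, cv_r2 = m@cvR2,
    n_train = m@nTrain, y_max = m@yMax,
    training_hash = trainingHash)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.num <- function(x) as.numeric(unlist(x))

#' Read a calibration model written by \code{\link{writeCalibrationModel}}
#'
#' @param path path to the JSON document.
#' @return A \linkS4class{CalibrationModel}.
#' @export
readCalibrationModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "RamanPAT-calibration-model"))
    stop("format error: not a calibration model document")
  steps <- lapply(doc$recipe$steps, function(st) {
    for (f in c("window", "polyorder", "deriv", "degree"))
      if (!is.null(st[[f]])) st[[f]] <- as.integer(st[[f]])
    if (!is.null(st$regions)) st$regions <- lapply(st$regions, .num)
    if (!is.null(st$anchor)) st$anchor <- as.numeric(st$anchor)
    if (!is.null(st$halfwidth)) st$halfwidth <- as.numeric(st$halfwidth)
    st
  })
  asMat <- function(x) do.call(rbind, lapply(x, .num))  # JSON rows -> matrix
  new("CalibrationModel",
      analyte = doc$analyte, units = doc$units,
      recipe = PreprocessRecipe(doc$recipe$name, steps),
      wavenumbers = .num(doc$wavenumbers),
      A = as.integer(doc$A),
      xMean = .num(doc$x_mean), yMean = .num(doc$y_mean),
      weights = asMat(doc$weights),
      xLoadings = asMat(doc$x_loadings),
      yLoadings = .num(doc$y_loadings),
      coefficients = .num(doc$coefficients),
      cvRmse = .num(doc$cv_rmse), cvR2 = .num(doc$cv_r2),
      nTrain = as.integer(doc$n_train), yMax = as.numeric(doc$y_max))
}
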