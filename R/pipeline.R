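# Apply a recipe, skipping (and logging) individual spectra a step cannot
# process instead of failing the whole series: an online run can contain
# acquisition gaps or dead spectra and monitoring must tolerate holes.
.applyRecipeSafe <- function(s, r) {
  if (is.character(r)) r <- builtinRecipe(r)
  skipped <- integer()
  messages <- character()
  keepIdx <- seq_len(nSpectra(s))
  for (i in seq_along(r@steps)) {
    st <- r@steps[[i]]
    if (st$kind == "peak_normalize") {
      hw <- st$halfwidth %||% 16
      win <- which(abs(s@wavenumbers - st$anchor) <= hw)
      bad <- if (length(win))
        which(apply(s@intensities[, win, drop = FALSE], 1L, max) <= 0)
      else integer()
      if (length(bad)) {
        messages <- c(messages, sprintf(
          "step %d (peak_normalize): skipped %d spectra with window max <= 0",
          i, length(bad)))
        skipped <- c(skipped, keepIdx[bad])
        s <- .dropSpectra(s, bad); keepIdx <- keepIdx[-bad]
      }
    }
    if (st$kind == "emsc") {
      ref <- Spectrum(s@wavenumbers, colMeans(s@intensities))
      D <- cbind(ref@intensities, .legendreBasis(s@wavenumbers, st$degree))
      b <- qr.coef(qr(D), t(s@intensities))[1L, ]
      bad <- which(abs(b) < 1e-10)
      if (length(bad)) {
        messages <- c(messages, sprintf(
          "step %d (emsc): skipped %d spectra with degenerate fit",
          i, length(bad)))
        skipped <- c(skipped, keepIdx[bad])
        s <- .dropSpectra(s, bad); keepIdx <- keepIdx[-bad]
      }
    }
    s <- applyRecipe(s, PreprocessRecipe(r@name, r@steps[i]))
  }
  list(spectra = s, skipped = sort(skipped), messages = messages)
}

.dropSpectra <- function(s, idx) {
  SpectraSet(s@wavenumbers, s@intensities[-idx, , drop = FALSE],
             s@times[-idx],
             labels = if (length(s@labels)) s@labels[-idx] else character(),
             provenance = s@provenance)
}

.writeManifest <- function(path, config, files) {
  yaml::write_yaml(list(
    package = "RamanPAT",
    version = as.character(utils::packageVersion("RamanPAT")),
    config = config,
    files = as.list(tools::md5sum(files))), path)
  invisible(path)
}

#' Simulate a fermentation run and write its files
#'
#' Wraps \code{\link{generateRun}}: writes the online spectra, HTS spectra,
#' reference table and ground-truth trajectories as CSV plus a YAML
#' manifest (config echo, seed, file checksums) into \code{outDir}.
#'
#' @param config \code{"rhodotorula_glucose"} or
#'   \code{"schizochytrium_glycerol"}.
#' @param seed integer seed.
#' @param outDir output directory (created if missing).
#' @param replicate \code{"loop"} or \code{"control"}.
#' @param ... further arguments to \code{\link{generateRun}}.
#' @return Invisibly, a named character vector of the files written.
#' @export
runSimulate <- function(config, seed, outDir, replicate = "loop", ...) {
  run <- generateRun(config, seed = seed, replicate = replicate, ...)
  if (!dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
    message("created output directory ", outDir)
  }
  fp <- function(f) file.path(outDir, f)
  files <- c(online = fp("online_spectra.csv"),
             hts_raman = fp("hts_raman_spectra.csv"),
             hts_ftir = fp("hts_ftir_spectra.csv"),
             reference = fp("reference.csv"),
             truth = fp("ground_truth.csv"))
  writeSpectraCSV(run$online, files[["online"]])
  writeSpectraCSV(run$hts$raman, files[["hts_raman"]])
  writeSpectraCSV(run$hts$ftir, files[["hts_ftir"]])
  writeReferenceCSV(run$reference, files[["reference"]])
  utils::write.csv(run$truth, files[["truth"]], row.names = FALSE)
  .writeManifest(fp("manifest.yaml"),
                 config = list(config = config, seed = seed,
                               replicate = replicate),
                 files = files)
  invisible(c(files, manifest = fp("manifest.yaml")))
}

#' Calibrate PLSR models for every analyte of a reference table
#'
#' Preprocesses the spectra with one recipe, aligns them to the reference
#' sampling timepoints, and fits one PLS1 model per analyte with
#' one-sample-out cross-validation and RMSE-optimal component selection.
#' Timepoints with a missing value are dropped per-analyte, not globally.
#'
#' @param spectra a \linkS4class{SpectraSet} or path to a wide spectra CSV.
#' @param reference a \linkS4class{ReferenceTable} or path to a long-form
#'   reference CSV.
#' @param recipe a \linkS4class{PreprocessRecipe} or built-in recipe name.
#' @param analyteNames analytes to calibrate (default: all in the table).
#' @param policy,windowH alignment policy and window, see
#'   \code{\link{alignToReference}}.
#' @param aMax largest candidate component count (default
#'   \code{min(10, n-2)}).
#' @param outDir optional directory; when given, one model JSON per analyte
#'   plus \code{calibration_report.csv} are written there.
#' @return A list with \code{models} (named list of
#'   \linkS4class{CalibrationModel}) and \code{report} (data.frame with
#'   analyte, units, n, range, R2_CV, Aopt, RMSE_CV, RMSE percent-of-max,
#'   and the rendered "RMSE (pct)" display cell).
#' @export
runCalibrate <- function(spectra, reference, recipe,
                         analyteNames = NULL, policy = "mean",
                         windowH = 0.5, aMax = NULL, outDir = NULL) {
  if (is.character(spectra)) spectra <- readSpectraCSV(spectra)
  if (is.character(reference)) reference <- readReferenceCSV(reference)
  if (is.character(recipe)) recipe <- builtinRecipe(recipe)
  if (is.null(analyteNames)) analyteNames <- analytes(reference)
  missing <- setdiff(analyteNames, analytes(reference))
  if (length(missing))
    stop("validation error: analyte(s) not in reference table: ",
         paste(missing, collapse = ", "))
  pre <- applyRecipe(spectra, recipe)
  al <- alignToReference(pre, reference, windowH = windowH, policy = policy)
  models <- list()
  rows <- list()
  for (a in analyteNames) {
    y <- al$y[, a]
    ok <- !is.na(y)
    X <- al$X[ok, , drop = FALSE]; ya <- y[ok]
    n <- length(ya)
    Am <- if (is.null(aMax)) min(10L, n - 2L) else min(aMax, n - 2L)
    cv <- looCv(X, ya, Am)
    Aopt <- selectComponents(cv$rmse)
    m <- plsrFit(X, ya, Aopt, analyte = a,
                 units = analyteUnits(reference)[[a]], recipe = recipe,
                 wavenumbers = al$wavenumbers, cvRmse = cv$rmse,
                 cvR2 = cv$r2)
    models[[a]] <- m
    pct <- rmsePctOfMax(cv$rmse[Aopt], ya)
    rows[[a]] <- data.frame(
      analyte = a, units = analyteUnits(reference)[[a]], n = n,
      range = sprintf("%.2f-%.2f", min(ya), max(ya)),
      r2_cv = cv$r2[Aopt], Aopt = Aopt, rmse_cv = cv$rmse[Aopt],
      rmse_pct_of_max = pct,
      display = formatRmseCell(cv$rmse[Aopt], ya),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (a in names(models)) {
      h <- .md5Object(list(al$X, al$y[, a]))
      writeCalibrationModel(models[[a]],
                            file.path(outDir, paste0("model_", a, ".json")),
                            trainingHash = h)
    }
    utils::write.csv(report, file.path(outDir, "calibration_report.csv"),
                     row.names = FALSE)
  }
  list(models = models, report = report)
}

#' Predict full-time-course concentration profiles
#'
#' Applies each model's recipe to the spectral time series and predicts the
#' analyte for every spectrum timestamp. Spectra an individual recipe step
#' cannot process are skipped and logged, not fatal.
#'
#' @param models a named list of \linkS4class{CalibrationModel}s, or paths
#'   to model JSON files.
#' @param spectra a \linkS4class{SpectraSet} or path to a wide spectra CSV.
#' @param outPath optional path for the long-form CSV
#'   (\code{time_h, analyte, units, value}).
#' @return A long-form data.frame of predictions.
#' @export
runMonitor <- function(models, spectra, outPath = NULL) {
  if (is.character(models))
    models <- stats::setNames(lapply(models, readCalibrationModel),
                              vapply(models, function(f)
                                readCalibrationModel(f)@analyte, ""))
  if (is.character(spectra)) spectra <- readSpectraCSV(spectra)
  out <- list()
  for (a in names(models)) {
    m <- models[[a]]
    safe <- .applyRecipeSafe(spectra, m@recipe)
    for (msg in safe$messages) message("[", a, "] ", msg)
    pre <- safe$spectra
    if (nChannels(pre) != length(m@xMean))
      stop(sprintf("shape error: recipe yields %d channels, model expects %d",
                   nChannels(pre), length(m@xMean)))
    yhat <- plsrPredict(m, intensities(pre))
    out[[a]] <- data.frame(time_h = acquisitionTimes(pre), analyte = a,
                           units = m@units, value = yhat,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(outPath))
    utils::write.csv(res, outPath, row.names = FALSE)
  res
}

#' Validate calibration models on an independent bioreplicate
#'
#' Preprocesses the test spectra with each model's recipe, aligns them to
#' the test reference table, and reports test-set R^2 / RMSE / RMSE
#' percent-of-max per analyte. Symmetric invocation (train on control, test
#' on loop, and vice versa) is supported by simply swapping the inputs.
#' Aborts if the model's units disagree with the test table's units.
#'
#' @param models named list of \linkS4class{CalibrationModel}s or paths.
#' @param spectra test \linkS4class{SpectraSet} or spectra CSV path.
#' @param reference test \linkS4class{ReferenceTable} or CSV path.
#' @param policy,windowH alignment parameters.
#' @return data.frame with analyte, units, n, r2_test, rmse_test and RMSE
#'   percent-of-max.
#' @export
runValidate <- function(models, spectra, reference, policy = "mean",
                        windowH = 0.5) {
  if (is.character(models))
    models <- stats::setNames(lapply(models, readCalibrationModel),
                              vapply(models, function(f)
                                readCalibrationModel(f)@analyte, ""))
  if (is.character(spectra)) spectra <- readSpectraCSV(spectra)
  if (is.character(reference)) reference <- readReferenceCSV(reference)
  rows <- list()
  for (a in names(models)) {
    m <- models[[a]]
    if (!a %in% analytes(reference))
      stop("validation error: analyte '", a, "' not in test reference")
    if (!identical(m@units, analyteUnits(reference)[[a]]))
      stop(sprintf("unit mismatch for '%s': model is %s, test table is %s",
                   a, m@units, analyteUnits(reference)[[a]]))
    pre <- applyRecipe(spectra, m@recipe)
    al <- alignToReference(pre, reference, windowH = windowH,
                           policy = policy)
    rep <- validateOnTest(m, al$X, al$y[, a])
    rows[[a]] <- data.frame(analyte = a, units = m@units, n = rep@n,
                            r2_test = rep@r2, rmse_test = rep@rmse,
                            rmse_pct_of_max = rep@rmsePctOfMax,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
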