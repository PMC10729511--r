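# run code with a local, seeded RNG stream, restoring the caller's state
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Instrument noise model for the spectra generator
#'
#' Models the artifacts the scatter-correction preprocessing exists to
#' remove: a per-spectrum log-normal multiplicative factor (turbidity,
#' laser-power variation), a slowly varying per-spectrum polynomial
#' baseline (fluorescence drift), and iid additive detector noise. All
#' randomness is reproducible from the seed.
#'
#' @param additiveSd additive noise sd in intensity units, or \code{NULL}
#'   to use \code{additiveRelSd} times the maximum clean signal.
#' @param additiveRelSd relative additive sd (default 0.005).
#' @param scatterSd sd of the log multiplicative factor (default 0.1).
#' @param baselineDegree polynomial degree of the drift (default 2).
#' @param baselineRelSd drift coefficient sd relative to the maximum clean
#'   signal (default 0.01).
#' @param seed integer seed.
#' @return A list of class \code{NoiseModel}.
#' @export
noiseModel <- function(additiveSd = NULL, additiveRelSd = 0.005,
                       scatterSd = 0.1, baselineDegree = 2L,
                       baselineRelSd = 0.01, seed = 1L) {
  stopifnot(additiveRelSd >= 0, scatterSd >= 0, baselineRelSd >= 0,
            baselineDegree >= 0)
  structure(list(additiveSd = additiveSd, additiveRelSd = additiveRelSd,
                 scatterSd = scatterSd,
                 baselineDegree = as.integer(baselineDegree),
                 baselineRelSd = baselineRelSd, seed = as.integer(seed)),
            class = "NoiseModel")
}

#' Render an online spectral time series from trajectories
#'
#' One spectrum per cadence tick over the trajectory span (inclusive of
#' t = 0): \code{raw(t) = m(t) [sum_c conc_c(t) response_c pure_c + water +
#' glass] + drift(t) + noise}, with water and glass at constant unit
#' "concentration". Deterministic given the noise model's seed.
#'
#' @param traj trajectory data.frame from \code{\link{simulateKinetics}}.
#' @param lib a \code{ComponentLibrary}.
#' @param grid wavenumber grid, cm^-1.
#' @param cadenceMin acquisition cadence in minutes (default 20).
#' @param noise a \code{NoiseModel}, or \code{NULL} for a noise-free render.
#' @return A \linkS4class{SpectraSet} with label \code{"online-raman"}.
#' @export
renderSpectra <- function(traj, lib, grid, cadenceMin = 20, noise = NULL) {
  stopifnot(inherits(lib, "ComponentLibrary"), cadenceMin > 0)
  times <- seq(0, max(traj$time_h), by = cadenceMin / 60)
  conc <- cbind(
    substrate = stats::approx(traj$time_h, traj$S, times)$y,
    biomass = stats::approx(traj$time_h, traj$X, times)$y,
    lipid = stats::approx(traj$time_h, traj$lipid_conc, times)$y,
    carotenoid = stats::approx(traj$time_h, traj$carotenoid_conc, times)$y,
    water = 1, glass = 1)
  comps <- colnames(conc)
  pure <- vapply(comps, function(nm)
    intensities(pureComponentSpectrum(lib, nm, grid)),
    numeric(length(grid)))                       # p x 6, descending axis
  amp <- sweep(conc, 2L, lib$response[comps], `*`)
  clean <- amp %*% t(pure)                       # n x p
  w <- sort(as.numeric(grid), decreasing = TRUE)
  if (is.null(noise)) {
    return(SpectraSet(w, clean, times, labels = rep("online-raman",
                                                    length(times)),
                      provenance = "simulated(noise-free)"))
  }
  n <- length(times); p <- length(w)
  mx <- max(clean)
  addSd <- noise$additiveSd %||% (noise$additiveRelSd * mx)
  out <- .withSeed(noise$seed, {
    m <- exp(stats::rnorm(n, 0, noise$scatterSd))
    B <- .legendreBasis(w, noise$baselineDegree)
    coefs <- matrix(stats::rnorm(n * (noise$baselineDegree + 1L), 0,
                                 noise$baselineRelSd * mx),
                    n, noise$baselineDegree + 1L)
    eps <- matrix(stats::rnorm(n * p, 0, addSd), n, p)
    clean * m + coefs %*% t(B) + eps
  })
  SpectraSet(w, out, times, labels = rep("online-raman", length(times)),
             provenance = "simulated")
}

#' Sample a reference table from trajectories with measurement noise
#'
#' True trajectory values at the sampling timepoints, perturbed by
#' multiplicative Gaussian noise of the stated coefficient of variation and
#' clamped at zero. Analytes and units follow the offline reference
#' analytics: substrate (g/L), cell dry weight (g/L), total lipids (g/L and
#' \%w/w), total carotenoids (mg/L and permille w/w).
#'
#' @param traj trajectory data.frame from \code{\link{simulateKinetics}}.
#' @param timepoints sampling times in hours, within the trajectory span.
#' @param cvPct per-analyte coefficient of variation in percent: named
#'   vector with entries \code{substrate}, \code{cdw}, \code{lipids},
#'   \code{carotenoids}, or a single number for all.
#' @param seed integer seed.
#' @param substrateName analyte name for the substrate column.
#' @return A \linkS4class{ReferenceTable}.
#' @export
makeReferenceTable <- function(traj, timepoints,
                               cvPct = c(substrate = 1.5, cdw = 2,
                                         lipids = 4, carotenoids = 4),
                               seed = 1L, substrateName = "glucose") {
  timepoints <- as.numeric(timepoints)
  if (min(timepoints) < min(traj$time_h) ||
      max(timepoints) > max(traj$time_h))
    stop("range error: timepoint(s) outside the trajectory span")
  if (length(cvPct) == 1L && is.null(names(cvPct)))
    cvPct <- c(substrate = cvPct, cdw = cvPct, lipids = cvPct,
               carotenoids = cvPct)
  at <- function(col) stats::approx(traj$time_h, traj[[col]], timepoints)$y
  true <- cbind(at("S"), at("X"), at("lipid_conc"), at("lipid_content"),
                at("carotenoid_conc"), at("carotenoid_content"))
  colnames(true) <- c(substrateName, "cdw", "total_lipids",
                      "total_lipids_content", "total_carotenoids",
                      "total_carotenoids_content")
  cv <- c(cvPct[["substrate"]], cvPct[["cdw"]], cvPct[["lipids"]],
          cvPct[["lipids"]], cvPct[["carotenoids"]], cvPct[["carotenoids"]])
  noisy <- .withSeed(seed, {
    true * (1 + matrix(stats::rnorm(length(true)), nrow(true), ncol(true)) *
              rep(cv / 100, each = nrow(true)))
  })
  noisy <- pmax(noisy, 0)
  ReferenceTable(timepoints, noisy,
                 units = c("g/L", "g/L", "g/L", "%w/w", "mg/L",
                           "permille_w/w"))
}

.samplingSchedule <- function(config) {
  switch(config,
         rhodotorula_glucose = c(4, 8, 12, 16, 20, 24, 32, 40, 48, 72, 96,
                                 120),
         schizochytrium_glycerol = c(8, 16, 24, 30, 36, 42, 48, 60, 72, 84,
                                     96, 120))
}

.defaultGrid <- function(config = "rhodotorula_glucose") {
  # online digital resolution: 1.928 cm^-1 (glucose run), 3.856 (glycerol)
  by <- if (config == "schizochytrium_glycerol") 3.856 else 1.928
  seq(3785, 650, by = -by)
}

.perturbKinetics <- function(p, seed) {
  .withSeed(seed, {
    q <- p
    q$mu <- p$mu * (1 + stats::runif(1, -0.01, 0.01))
    for (f in c("X0", "K", "S0", "Yxs"))
      q[[f]] <- p[[f]] * (1 + stats::runif(1, -0.01, 0.01))
    q$Yxs <- min(q$Yxs, 1)
    q
  })
}

# HTS (at-line) spectra of withdrawn biomass: per-gram composition mixture
# (biomass matrix + lipid and carotenoid content), no water/glass bands.
.renderHts <- function(traj, lib, grid, timepoints, modality, seed,
                       addRelSd = 0.005) {
  at <- function(col) stats::approx(traj$time_h, traj[[col]], timepoints)$y
  comps <- c("biomass", "lipid", "carotenoid")
  pure <- vapply(comps, function(nm)
    intensities(pureComponentSpectrum(lib, nm, grid)),
    numeric(length(grid)))
  amp <- cbind(biomass = 1,
               lipid = at("lipid_content") / 100,
               carotenoid = at("carotenoid_content"))
  amp <- sweep(amp, 2L, lib$response[comps], `*`)
  clean <- amp %*% t(pure)
  w <- sort(as.numeric(grid), decreasing = TRUE)
  noisy <- .withSeed(seed, {
    clean + matrix(stats::rnorm(length(clean), 0, addRelSd * max(clean)),
                   nrow(clean), ncol(clean))
  })
  SpectraSet(w, noisy, timepoints,
             labels = rep(modality, length(timepoints)),
             provenance = sprintf("simulated(%s)", modality))
}

#' Generate a complete synthetic fermentation run
#'
#' Produces everything the undeposited raw data would have provided: the
#' online FT-Raman time series (20-min cadence over 120 h, 361 spectra),
#' at-line HTS Raman and FTIR spectra of the withdrawn biomass at the
#' sampling timepoints, a noisy offline reference table, and the exact
#' ground-truth trajectories for recovery scoring. The two replicates
#' (\code{"loop"}: the reactor carrying the flow cell; \code{"control"})
#' share kinetics up to small (<= 2\%) seeded parameter perturbations,
#' emulating a duplicate-reactor design used for test-set validation.
#'
#' @param config \code{"rhodotorula_glucose"} or
#'   \code{"schizochytrium_glycerol"}.
#' @param seed integer seed; all randomness derives from it.
#' @param replicate \code{"loop"} (default) or \code{"control"}.
#' @param tEnd fermentation duration in hours (default 120).
#' @param cadenceMin online acquisition cadence in minutes (default 20).
#' @param noise a \code{NoiseModel} or \code{NULL} for the default model.
#' @param cvPct reference measurement CVs, see
#'   \code{\link{makeReferenceTable}}.
#' @return A list with elements \code{online} (\linkS4class{SpectraSet}),
#'   \code{hts} (list of \code{raman} and \code{ftir} SpectraSets),
#'   \code{reference} (\linkS4class{ReferenceTable}), \code{truth}
#'   (trajectory data.frame on the online time grid), \code{kinetics},
#'   \code{library}, \code{config}, \code{seed}, \code{replicate}.
#' @export
generateRun <- function(config = c("rhodotorula_glucose",
                                   "schizochytrium_glycerol"),
                        seed = 1L, replicate = c("loop", "control"),
                        tEnd = 120, cadenceMin = 20, noise = NULL,
                        cvPct = c(substrate = 1.5, cdw = 2, lipids = 4,
                                  carotenoids = 4)) {
  config <- match.arg(config)
  replicate <- match.arg(replicate)
  seed <- as.integer(seed)
  p <- defaultKinetics(config)
  if (replicate == "control")
    p <- .perturbKinetics(p, seed = seed + 7919L)
  grid <- .defaultGrid(config)
  times <- seq(0, tEnd, by = cadenceMin / 60)
  traj <- simulateKinetics(p, times)
  lib <- defaultComponentLibrary(p$substrate)
  repOff <- if (replicate == "loop") 0L else 500000L
  if (is.null(noise)) noise <- noiseModel(seed = seed + 1000L + repOff)
  online <- renderSpectra(traj, lib, grid, cadenceMin, noise)
  tp <- .samplingSchedule(config)
  tp <- tp[tp <= tEnd]
  reference <- makeReferenceTable(traj, tp, cvPct = cvPct,
                                  seed = seed + 2000L + repOff,
                                  substrateName = p$substrate)
  hts <- list(
    raman = .renderHts(traj, lib, grid, tp, "hts-raman",
                       seed = seed + 3000L + repOff),
    ftir = .renderHts(traj, lib, grid, tp, "hts-ftir",
                      seed = seed + 4000L + repOff))
  list(online = online, hts = hts, reference = reference, truth = traj,
       kinetics = p, library = lib, config = config, seed = seed,
       replicate = replicate)
}
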