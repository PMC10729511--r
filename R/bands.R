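#' Describe one vibrational band
#'
#' @param center band center, cm^-1.
#' @param fwhm full width at half maximum, cm^-1 (> 0).
#' @param height peak height, relative intensity (>= 0).
#' @param shape \code{"gaussian"} or \code{"lorentzian"}.
#' @return A list of class \code{BandSpec}.
#' @export
bandSpec <- function(center, fwhm, height,
                     shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("validation error: fwhm must be > 0")
  if (height < 0) stop("validation error: height must be >= 0")
  structure(list(center = center, fwhm = fwhm, height = height,
                 shape = shape), class = "BandSpec")
}

.evalBand <- function(b, grid) {
  d <- grid - b$center
  if (b$shape == "gaussian")
    b$height * exp(-4 * log(2) * d^2 / b$fwhm^2)
  else
    b$height * (b$fwhm / 2)^2 / (d^2 + (b$fwhm / 2)^2)
}

#' Build a component band library
#'
#' @param components named list; each element a list of \code{BandSpec}s
#'   (>= 2 bands per component).
#' @param response named numeric, signal per unit concentration per
#'   component (intensity*L/g; carotenoids in intensity*L/mg including any
#'   resonance-enhancement multiplier). All > 0.
#' @return A list of class \code{ComponentLibrary}.
#' @export
componentLibrary <- function(components, response) {
  if (any(vapply(components, length, 1L) < 2L))
    stop("validation error: every component needs >= 2 bands")
  if (any(response[names(components)] <= 0) ||
      !all(names(components) %in% names(response)))
    stop("validation error: positive response required per component")
  structure(list(components = components, response = response),
            class = "ComponentLibrary")
}

#' Default band library for fermentation broth spectra
#'
#' Band positions follow the standard assignments for these systems:
#' substrate C-H stretches at 2950/2896 cm^-1, CH2 bending near 1461
#' (glucose) / 1467 (glycerol) cm^-1, glucose CH2 wagging in 1370-1320 and
#' C-OH modes in 1130-1020 cm^-1, glycerol C-OH/CH2 twisting in 1120-1050
#' and skeletal C-C at 860 cm^-1; lipid C-H stretch at 2855/2925, ester C=O
#' at 1746, C=C at 1655, scissoring near 1448, CH2 twist at 1303 cm^-1;
#' carotenoid C=C at 1515 and C-C/C-H at 1152 cm^-1 (resonance-enhanced);
#' water O-H stretch around 3400-3000 and H-O-H bend at 1645 cm^-1;
#' borosilicate glass Si-O bands at 1100-900 and 800 cm^-1. Heights and
#' widths are the generator's own (fingerprint bands 12-40 cm^-1 FWHM,
#' CH/OH-stretch bands 50-300 cm^-1).
#'
#' @param substrate \code{"glucose"} or \code{"glycerol"}.
#' @param carotenoidEnhancement resonance multiplier applied to the
#'   carotenoid response (default 50; at 1064 nm excitation the resonance
#'   effect is present but relatively weak).
#' @return A \code{ComponentLibrary} with components \code{substrate},
#'   \code{biomass}, \code{lipid}, \code{carotenoid}, \code{water},
#'   \code{glass}.
#' @export
defaultComponentLibrary <- function(substrate = c("glucose", "glycerol"),
                                    carotenoidEnhancement = 50) {
  substrate <- match.arg(substrate)
  g <- function(center, fwhm, height) bandSpec(center, fwhm, height)
  subBands <- if (substrate == "glucose") list(
    g(2950, 60, 0.80), g(2896, 55, 0.90), g(1461, 25, 0.50),
    g(1345, 35, 0.60), g(1125, 30, 0.70), g(1065, 35, 0.80))
  else list(
    g(2954, 60, 0.80), g(2896, 55, 0.90), g(1467, 25, 0.60),
    g(1085, 40, 0.80), g(1056, 30, 0.70), g(860, 20, 0.90))
  componentLibrary(
    components = list(
      substrate = subBands,
      biomass = list(g(2935, 70, 0.90), g(1658, 35, 0.60),
                     g(1448, 30, 0.50), g(1003, 12, 0.70)),
      lipid = list(g(2925, 50, 0.70), g(2855, 40, 1.00),
                   bandSpec(1746, 25, 0.30, "lorentzian"),
                   g(1655, 30, 0.50), g(1448, 25, 0.60),
                   g(1303, 25, 0.50)),
      carotenoid = list(g(1515, 25, 1.00), g(1152, 20, 0.70),
                        g(1005, 15, 0.40)),
      water = list(g(3230, 300, 1.00), g(1645, 80, 0.25)),
      glass = list(g(1040, 120, 0.60), g(800, 60, 1.00))),
    response = c(substrate = 1.0, biomass = 1.2, lipid = 1.5,
                 carotenoid = 0.001 * carotenoidEnhancement,
                 water = 30, glass = 20))
}

#' Evaluate a pure component spectrum on a grid
#'
#' Sum of the component's band profiles (unit response; concentration
#' scaling is applied at render time).
#'
#' @param lib a \code{ComponentLibrary}.
#' @param name component name.
#' @param grid wavenumber grid, cm^-1.
#' @return A \linkS4class{Spectrum}.
#' @export
pureComponentSpectrum <- function(lib, name, grid) {
  stopifnot(inherits(lib, "ComponentLibrary"))
  if (!name %in% names(lib$components))
    stop("lookup error: unknown component '", name, "'; available: ",
         paste(names(lib$components), collapse = ", "))
  grid <- as.numeric(grid)
  y <- Reduce(`+`, lapply(lib$components[[name]], .evalBand, grid = grid))
  Spectrum(grid, y)
}
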