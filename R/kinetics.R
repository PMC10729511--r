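#' Fermentation kinetics parameters
#'
#' Closed-form batch-fermentation kinetics: logistic biomass growth,
#' yield-coupled substrate consumption, logistic intracellular lipid
#' accumulation, and a smooth carotenoid content peak that decays to a
#' terminal fraction (carotenogenic yeasts partially degrade pigments late
#' in the batch).
#'
#' @param X0 inoculum biomass, g/L CDW.
#' @param K biomass carrying capacity, g/L.
#' @param mu specific growth rate, 1/h.
#' @param S0 initial carbon substrate, g/L.
#' @param Yxs biomass yield on substrate, g/g (<= 1).
#' @param Lmax maximum lipid content, \%w/w.
#' @param tMid time of half-maximal lipid content, h.
#' @param Lslope lipid logistic slope, 1/h.
#' @param Cmax peak carotenoid content, permille w/w.
#' @param tPeak time of the carotenoid peak, h.
#' @param CriseH,CdecayH Gaussian widths of the rise and decay flanks, h.
#' @param CterminalFrac fraction of the peak content retained at late times.
#' @param substrate substrate name ("glucose" or "glycerol").
#' @return A validated list of class \code{KineticsParams}.
#' @seealso \code{\link{defaultKinetics}}, \code{\link{simulateKinetics}}
#' @export
kineticsParams <- function(X0, K, mu, S0, Yxs, Lmax, tMid, Lslope,
                           Cmax, tPeak, CriseH, CdecayH, CterminalFrac,
                           substrate = "glucose") {
  p <- list(X0 = X0, K = K, mu = mu, S0 = S0, Yxs = Yxs, Lmax = Lmax,
            tMid = tMid, Lslope = Lslope, Cmax = Cmax, tPeak = tPeak,
            CriseH = CriseH, CdecayH = CdecayH,
            CterminalFrac = CterminalFrac, substrate = substrate)
  pos <- c("X0", "K", "S0", "Yxs", "Lmax", "tMid", "Lslope", "Cmax",
           "tPeak", "CriseH", "CdecayH")
  if (any(!vapply(p[pos], function(v) is.numeric(v) && v > 0, TRUE)))
    stop("validation error: kinetic parameters must be positive")
  if (!is.numeric(mu) || mu < 0)
    stop("validation error: mu must be >= 0")
  if (CterminalFrac <= 0 || CterminalFrac > 1)
    stop("validation error: CterminalFrac must be in (0, 1]")
  if (X0 >= K) stop("validation error: X0 must be < K")
  if (Yxs > 1) stop("validation error: Yxs must be <= 1")
  class(p) <- "KineticsParams"
  p
}

#' Default kinetics for the two reference fermentations
#'
#' \code{rhodotorula_glucose}: batch glucose fermentation by an oleaginous,
#' carotenogenic yeast; 52.2 g/L glucose fully consumed within 120 h, final
#' biomass 18.3 g/L CDW, lipid content saturating at 66.3 \%w/w around
#' 96 h, carotenoid content peaking at 12.25 permille w/w at 48 h and
#' declining to about 9 permille. \code{schizochytrium_glycerol}: batch
#' glycerol fermentation by a marine thraustochytrid; 55 g/L glycerol, 77\%
#' consumed at 120 h, final biomass 26.4 g/L, lipid content up to 43.7
#' \%w/w, small carotenoid peak (0.40 permille) at 30 h.
#'
#' @param config \code{"rhodotorula_glucose"} or
#'   \code{"schizochytrium_glycerol"}.
#' @return A \code{KineticsParams} list.
#' @export
defaultKinetics <- function(config = c("rhodotorula_glucose",
                                       "schizochytrium_glycerol")) {
  config <- match.arg(config)
  if (config == "rhodotorula_glucose")
    kineticsParams(X0 = 0.55, K = 20, mu = 0.07, S0 = 52.2, Yxs = 0.34,
                   Lmax = 66.3, tMid = 40, Lslope = 0.09,
                   Cmax = 12.25, tPeak = 48, CriseH = 18, CdecayH = 30,
                   CterminalFrac = 0.733, substrate = "glucose")
  else
    kineticsParams(X0 = 2.0, K = 30, mu = 0.0386, S0 = 55, Yxs = 0.576,
                   Lmax = 43.7, tMid = 24, Lslope = 0.15,
                   Cmax = 0.40, tPeak = 30, CriseH = 12, CdecayH = 40,
                   CterminalFrac = 0.825, substrate = "glycerol")
}

#' Simulate fermentation trajectories
#'
#' Biomass follows the logistic law
#' \code{X(t) = K X0 e^(mu t) / (K + X0 (e^(mu t) - 1))}, substrate is
#' yield-coupled, \code{S(t) = max(0, S0 - (X(t) - X0)/Yxs)}; once S hits 0
#' growth is clamped (stationary phase) and the output is flagged. Lipid
#' content is logistic in time capped at \code{Lmax}; carotenoid content is
#' a smooth Gaussian-flanked peak at \code{tPeak} decaying to
#' \code{CterminalFrac} of the peak. Concentrations are content times
#' biomass with unit conversions (\%w/w -> g/g: /100; permille w/w -> mg/g:
#' x1).
#'
#' @param p a \code{KineticsParams} list.
#' @param t increasing time grid in hours starting at 0.
#' @return A data.frame with columns \code{time_h}, \code{X} (g/L CDW),
#'   \code{S} (g/L), \code{lipid_content} (\%w/w), \code{lipid_conc} (g/L),
#'   \code{carotenoid_content} (permille w/w), \code{carotenoid_conc}
#'   (mg/L); attribute \code{clamped} is TRUE if substrate ran out before
#'   the end of the grid.
#' @export
simulateKinetics <- function(p, t) {
  stopifnot(inherits(p, "KineticsParams"))
  t <- as.numeric(t)
  if (t[1L] != 0 || (length(t) > 1 && any(diff(t) <= 0)))
    stop("validation error: t must be increasing and start at 0")
  e <- exp(p$mu * t)
  Xlog <- p$K * p$X0 * e / (p$K + p$X0 * (e - 1))
  Xcap <- p$X0 + p$S0 * p$Yxs          # biomass when substrate is exhausted
  clamped <- any(Xlog > Xcap)
  X <- pmin(Xlog, Xcap)
  S <- pmax(0, p$S0 - (X - p$X0) / p$Yxs)
  L <- p$Lmax / (1 + exp(-p$Lslope * (t - p$tMid)))
  f <- p$CterminalFrac
  C <- ifelse(t <= p$tPeak,
              p$Cmax * exp(-(t - p$tPeak)^2 / (2 * p$CriseH^2)),
              p$Cmax * (f + (1 - f) *
                          exp(-(t - p$tPeak)^2 / (2 * p$CdecayH^2))))
  out <- data.frame(time_h = t, X = X, S = S,
                    lipid_content = L, lipid_conc = L / 100 * X,
                    carotenoid_content = C, carotenoid_conc = C * X)
  attr(out, "clamped") <- clamped
  out
}
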