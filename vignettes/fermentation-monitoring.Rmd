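---
title: "Methods: online Raman calibration of fermentation processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: online Raman calibration of fermentation processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanPAT)
```

## Scope and data model

RamanPAT calibrates time-resolved vibrational spectra of fermentation broth
against sparse offline reference measurements and then predicts full
concentration time courses. The X-block is a `SpectraSet`: a shared
wavenumber axis in cm⁻¹ (stored strictly descending, the plotting convention
for Raman/IR), an intensity matrix with one row per acquisition, and
acquisition times in hours from inoculation. The y-block is a
`ReferenceTable`: per-timepoint analyte values with declared units (`g/L`,
`mg/L`, `%w/w`, `permille_w/w`); missing values are allowed and are dropped
per-analyte, never globally. The canonical interchange formats are a wide
CSV (first column `wavenumber_cm-1`, remaining headers decimal hours) and a
long reference CSV (`time_h, analyte, units, value`); single spectra can
also be read from single-block JCAMP-DX.

Spectra and reference samples are paired by `alignToReference`. The matching
rule is not something raw data dictates uniquely, so both natural policies
are exposed: `nearest` (single closest spectrum, ties to the earlier one)
and `mean` (unweighted average of all spectra within ±`windowH` hours). The
default is `mean` with `windowH = 0.5` h: a single 1024-scan FT-Raman
acquisition takes about 15 min, so a single spectrum is relatively noisy and
averaging the two or three acquisitions bracketing the sampling time is the
natural estimate of the broth state at that time.

## Pretreatment steps

**Rubber-band baseline.** The additive background (fluorescence, broad
scattering) is estimated as the lower convex hull of the (wavenumber,
intensity) point set, computed with Andrew's monotone chain, linearly
interpolated between hull vertices, and subtracted. This one-pass hull is
the canonical definition of the rubber band; it is idempotent (a second pass
yields a baseline ≤ 10⁻¹⁰), never exceeds the signal, and pins the corrected
spectrum to zero at both ends. Vendor implementations add an iterative
"number of baseline points" refinement whose exact behaviour is
undocumented; we deliberately do not imitate it. At least 3 channels are
required.

**Savitzky–Golay.** Local least-squares polynomial smoothing and
derivatives. Interior points use the closed convolution weights; the first
and last `(window-1)/2` points are refit on the truncated one-sided window
instead of reflect-padding, because padding fabricates out-of-range channels
on already-truncated regions. Derivatives are reported per (cm⁻¹)^deriv with
respect to *increasing* wavenumber on a uniform grid (index-space derivative
divided by spacing^deriv). Only relative spectral shape matters downstream —
PLSR is affine-invariant after centering — so this convention is recorded
rather than tuned. Defaults used by the built-in recipes: window 9,
polynomial 2, derivative 0 for online and HTS-Raman smoothing; window 15,
polynomial 2, derivative 2 for HTS-FTIR.

**Anchor-peak normalisation.** The spectrum is divided by the maximum
intensity within `anchor ± halfwidth`. The windowed maximum (halfwidth
default 16 cm⁻¹ ≈ two resolution elements at 8 cm⁻¹ spectral resolution) is
robust to grid offsets between instruments with different digital
resolutions, unlike a single nearest channel. The two meaningful anchors for
broth spectra through a glass flow cell are the glass band at 800 cm⁻¹
(internal standard, constant optical path) and the water band at 3200 cm⁻¹
(external standard, near-constant water concentration). We use the band
*height*, not an integral; an integral would be an equally defensible
choice, and the halfwidth parameter is the knob for sensitivity analysis. A
window maximum ≤ 0 is an error: it signals a baseline that was not removed
first, or a dead spectrum.

**EMSC.** Each spectrum is decomposed by ordinary least squares into
`b·reference + Σ aᵢPᵢ + e`, where `Pᵢ` are Legendre polynomials of order
0..d on the axis rescaled to [−1, 1]; the corrected spectrum is
`(raw − Σ aᵢPᵢ)/b`. Legendre (rather than monomial) terms keep the design
well conditioned at degree 6. "Linear and quadratic components" means
d = 2 — the constant is always included. The default reference is the mean
spectrum of the dataset being corrected; a fitted multiplicative factor with
|b| < 10⁻¹⁰ is a degenerate fit and is an error (or a skip, during
monitoring). Residuals are orthogonal to the design to ≤ 10⁻⁸ relative, and
correcting the reference itself is a fixed point — both are tested.

**Recipes.** Steps compose in strictly listed order with per-step
provenance. The built-ins mirror the standard pretreatment chains for each
modality: the online glass/water recipes baseline-correct, smooth, normalise
and *then* truncate; the online EMSC recipes baseline-correct, smooth,
truncate and then apply EMSC (degree 4 for the glucose run, degree 6 for the
glycerol run, which needs more baseline flexibility); the HTS-FTIR recipe
takes second derivatives, truncates to 3050–2800 and 1800–900 cm⁻¹, then
EMSC degree 2; the HTS-Raman recipe smooths, truncates to 3050–2500 and
1800–650 cm⁻¹, baselines, then EMSC degree 2. Truncation bounds are
inclusive on both ends.

## Calibration

PLS1 by NIPALS on mean-centered X and y, with no variance scaling: channels
share units after pretreatment, and y stays in native units so RMSE is
directly comparable across preprocessing variants. One-sample-out CV refits
the model inside every fold, *re-centering within the fold* (the
statistically correct choice; centering on the full data leaks the held-out
sample). Components are nested, so one NIPALS pass per fold yields
predictions for every candidate A. `Aopt = argmin RMSE_CV(A)` with ties
broken toward the smaller A (parsimony). `Amax` defaults to `min(10, n−2)`,
a safe ceiling when calibrations of this type use 1–8 components. R² is the
prediction-based `1 − SSE/SST`, which admits negative CV values and orders
models identically to RMSE.

If the residual covariance is exhausted before A components (X rank
deficient, or y fitted exactly), extraction stops and the coefficient vector
freezes at the last extracted component; requesting more components than the
rank through `plsrFit` is still an explicit rank error.

Reported percentages (`RMSE (x%)` cells) are `100·RMSE/max(reference)`,
rendered with round-half-up to one decimal. Rounding is display-only; the
machine-readable report keeps full precision. (Published tables of this form
are occasionally internally inconsistent by one unit in the last rendered
decimal for borderline values; we fix one convention — round-half-up — and
document it rather than imitate any single table.)

Cross-replicate validation (`runValidate`) applies a model unchanged to the
other bioreactor's spectra and reference table, symmetric in both
directions; analyte units must match exactly or the run aborts.

## The synthetic data generator

The generator stands in for undeposited raw data; it defines the study
conditions once and is not a tuning dial.

**Kinetics.** Biomass follows the logistic law with carrying capacity K;
substrate is yield-coupled, `S = max(0, S0 − (X − X0)/Yxs)`, with growth
clamped once substrate is exhausted (the clamp is flagged). Lipid content is
logistic in time, capped at `Lmax`; carotenoid content is a Gaussian-flanked
peak at `tPeak` decaying to a terminal fraction. These closed forms are the
package's own choice — real measured trajectories constrain only their
shapes (monotone biomass rise and substrate fall, lipid rise, carotenoid
peak-then-decline). Defaults are calibrated once to the published anchor
values of the two reference fermentations: glucose run — S0 = 52.2 g/L fully
consumed by 120 h, final CDW 18.3 g/L, lipid content saturating at
66.3 %w/w near 96 h, carotenoid content peaking at 12.25 ‰w/w at 48 h and
declining to ≈ 9 ‰w/w; glycerol run — S0 = 55 g/L with 77% consumed at
120 h and final CDW 26.4 g/L. With the glucose-run parameters the substrate
runs out near 85 h, so biomass plateaus earlier than in the real
fermentation; the endpoint anchors are what the defaults guarantee.

**Spectra.** Raw spectra are linear mixtures: concentration × response ×
pure-component spectrum, summed over substrate, biomass, lipid, carotenoid,
plus water and glass at constant unit amount, then scaled by a per-spectrum
log-normal scatter factor, shifted by a per-spectrum random degree-2
polynomial drift, plus iid additive noise. Band centers follow the
literature assignments (see `?defaultComponentLibrary`); heights, widths and
responses are invented, with the carotenoid response carrying a configurable
50× resonance-enhancement multiplier (resonance at 1064 nm excitation is
present but relatively weak). Defaults: additive sd 0.5% of the maximum
clean signal, scatter sd 0.1 on the log factor, drift coefficient sd 1% of
the maximum clean signal. The default grid is 3785–650 cm⁻¹ at 1.928 cm⁻¹
spacing (3.856 for the glycerol config), 20-min cadence over 120 h — 361
online spectra and 12 reference timepoints per run.

**Reference noise.** Offline measurements are perturbed multiplicatively
with per-analyte CVs chosen once for the character of each assay: 1.5%
(substrate, enzymatic kit/HPLC), 2% (CDW gravimetry), 4% (lipids by direct
transesterification + GC, a multi-step wet-chemistry chain), 4% (carotenoids
by extraction + HPLC). Negatives are clamped to zero.

**Replicates.** The `control` replicate perturbs the kinetic parameters by
≤ 1–2% (seeded), emulating a duplicate-reactor design; trajectories of the
two replicates agree pointwise to within 5% of their maxima by construction.

**What the generator does not emulate.** Physically rigorous Raman cross
sections, fluorescence photochemistry, cosmic rays, pH/DO/temperature
channels, fed-batch feeding, and the acquisition gaps of real campaigns.
Passing the recovery tests therefore demonstrates that the pipeline is
self-consistent and numerically correct under realistic artifact types — not
that any particular accuracy will be achieved on a given real instrument.

## Numerical choices and degenerate inputs

- Axis: strictly monotonic, stored descending; ascending input is flipped
  together with its intensities. Region bounds inclusive.
- Resampling is channel-wise linear interpolation, no extrapolation.
- EMSC degenerate-fit tolerance |b| < 10⁻¹⁰; orthogonality assertions at
  10⁻⁸ relative.
- `selectComponents` ties go to the smaller A; `which.min` semantics.
- Round-half-up (commercial rounding) for displayed percentages only.
- During monitoring, spectra an individual step cannot process (dead
  spectrum under peak normalisation, degenerate EMSC fit) are skipped and
  logged rather than aborting the run — online series legitimately contain
  holes.
- All generator randomness flows through explicit integer seeds; the
  caller's RNG state is saved and restored.

## Problem sizes

The test suite and the acceptance script run the full default-size pipeline
(361 × 1627 online spectra, 12 reference timepoints, LOO-CV up to 10
components for four analytes), which completes in seconds; oracle-equivalence
tests (O(n²) hull checks, brute-force CV refits) use 8–60-channel spectra
and n = 7–10 sample calibrations, sizes at which the oracles are exact and
instant.

## Known limitations

- The EMSC reference is the mean of the dataset being corrected, so a model
  applied to a new series implicitly re-estimates its reference; for
  transfer between very different series a stored training reference would
  be preferable.
- Savitzky–Golay assumes a uniform grid (resample first if needed).
- No scatter-correction variants beyond EMSC (no SNV), no despiking, no
  variable selection or PLS2, no uncertainty bands on predictions.
- The generator's component responses are unknowable from published
  summaries; recovery is therefore always scored against the generator's own
  ground truth, never against published calibration tables.
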