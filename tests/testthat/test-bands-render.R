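test_that("band profiles honour the FWHM parameterization", {
  grid <- seq(1600, 1400, by = -0.5)
  for (shape in c("gaussian", "lorentzian")) {
    lib <- componentLibrary(
      components = list(x = list(bandSpec(1500, 30, 2, shape),
                                 bandSpec(1300, 10, 0, shape))),
      response = c(x = 1))
    s <- pureComponentSpectrum(lib, "x", grid)
    at <- function(v) intensities(s)[which.min(abs(wavenumbers(s) - v))]
    expect_equal(at(1500), 2, tolerance = 1e-12)
    expect_equal(at(1515), 1, tolerance = 1e-9)   # center + FWHM/2
    expect_equal(at(1485), 1, tolerance = 1e-9)   # center - FWHM/2
  }
})

test_that("multi-band components are additive", {
  grid <- seq(2000, 600, by = -2)
  b1 <- bandSpec(1500, 30, 1); b2 <- bandSpec(900, 50, 2)
  lib <- componentLibrary(
    components = list(both = list(b1, b2),
                      one = list(b1, bandSpec(900, 50, 0)),
                      two = list(bandSpec(1500, 30, 0), b2)),
    response = c(both = 1, one = 1, two = 1))
  expect_equal(intensities(pureComponentSpectrum(lib, "both", grid)),
               intensities(pureComponentSpectrum(lib, "one", grid)) +
                 intensities(pureComponentSpectrum(lib, "two", grid)),
               tolerance = 1e-12)
})

test_that("unknown components and invalid band parameters error", {
  lib <- defaultComponentLibrary("glucose")
  expect_error(pureComponentSpectrum(lib, "caffeine", seq(1000, 900, -2)),
               "lookup error")
  expect_error(bandSpec(1000, -1, 1), "fwhm")
  expect_error(bandSpec(1000, 10, -1), "height")
})

test_that("noise-free renders are exact linear mixtures", {
  p <- defaultKinetics("rhodotorula_glucose")
  traj <- simulateKinetics(p, seq(0, 120, by = 1 / 3))
  lib <- defaultComponentLibrary("glucose")
  grid <- seq(3785, 650, by = -1.928)
  s <- renderSpectra(traj, lib, grid, cadenceMin = 20, noise = NULL)
  comps <- c("substrate", "biomass", "lipid", "carotenoid", "water",
             "glass")
  A <- vapply(comps, function(nm)
    intensities(pureComponentSpectrum(lib, nm, grid)) * lib$response[[nm]],
    numeric(length(grid)))
  # linear-solve oracle: recover concentrations from the known mixing system
  sol <- qr.solve(A, t(intensities(s)))
  idx <- match(acquisitionTimes(s), traj$time_h)
  expect_equal(sol["substrate", ], traj$S[idx], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sol["biomass", ], traj$X[idx], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sol["lipid", ], traj$lipid_conc[idx], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sol["carotenoid", ], traj$carotenoid_conc[idx],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a 120 h run at 20-min cadence yields 361 spectra", {
  run <- generateRun("rhodotorula_glucose", seed = 1)
  expect_equal(nSpectra(run$online), 361L)
  expect_equal(acquisitionTimes(run$online)[1], 0)
  expect_equal(max(acquisitionTimes(run$online)), 120)
})

test_that("rendering is deterministic given the seed", {
  p <- defaultKinetics("rhodotorula_glucose")
  traj <- simulateKinetics(p, seq(0, 20, by = 1 / 3))
  lib <- defaultComponentLibrary("glucose")
  grid <- seq(3000, 800, by = -4)
  nm <- noiseModel(seed = 99)
  a <- renderSpectra(traj, lib, grid, 20, nm)
  b <- renderSpectra(traj, lib, grid, 20, nm)
  expect_identical(intensities(a), intensities(b))
  c <- renderSpectra(traj, lib, grid, 20, noiseModel(seed = 100))
  expect_false(identical(intensities(a), intensities(c)))
})

test_that("reference tables sample the trajectories faithfully", {
  p <- defaultKinetics("rhodotorula_glucose")
  traj <- simulateKinetics(p, seq(0, 120, by = 1 / 3))
  tp <- c(4, 8, 12, 16, 20, 24, 32, 40, 48, 72, 96, 120)
  exact <- makeReferenceTable(traj, tp, cvPct = 0, seed = 1)
  expect_equal(referenceValues(exact)[, "glucose"],
               approx(traj$time_h, traj$S, tp)$y, ignore_attr = TRUE)
  expect_equal(referenceValues(exact)[, "cdw"],
               approx(traj$time_h, traj$X, tp)$y, ignore_attr = TRUE)
  # determinism and clamping
  n1 <- makeReferenceTable(traj, tp, cvPct = 50, seed = 5)
  n2 <- makeReferenceTable(traj, tp, cvPct = 50, seed = 5)
  expect_identical(referenceValues(n1), referenceValues(n2))
  expect_true(all(referenceValues(n1) >= 0))
  expect_error(makeReferenceTable(traj, c(4, 200)), "range error")
})

test_that("replicate runs share kinetics up to small perturbations", {
  loop <- generateRun("rhodotorula_glucose", seed = 1, replicate = "loop")
  ctrl <- generateRun("rhodotorula_glucose", seed = 1,
                      replicate = "control")
  dS <- abs(loop$truth$S - ctrl$truth$S) / max(loop$truth$S)
  expect_lte(max(dS), 0.05)
  dX <- abs(loop$truth$X - ctrl$truth$X) / max(loop$truth$X)
  expect_lte(max(dX), 0.05)
  expect_false(identical(loop$truth$S, ctrl$truth$S))
})

test_that("both configurations emit 12 reference timepoints and ground truth", {
  for (cfg in c("rhodotorula_glucose", "schizochytrium_glycerol")) {
    run <- generateRun(cfg, seed = 2, tEnd = 120)
    expect_equal(length(timepoints(run$reference)), 12L)
    expect_true(all(c("X", "S", "lipid_conc", "carotenoid_conc") %in%
                      names(run$truth)))
  }
  expect_error(generateRun("unknown_config", seed = 1))
})
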