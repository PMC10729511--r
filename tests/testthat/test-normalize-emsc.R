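test_that("peak normalization is scale-invariant and idempotent", {
  s <- randomSpectraSet(n = 3, p = 60, seed = 21, wmax = 1200, wmin = 600)
  # make the anchor window clearly positive
  X <- intensities(s) + 0.5
  s <- SpectraSet(wavenumbers(s), X, acquisitionTimes(s))
  norm1 <- peakNormalize(s, 800)
  scaled <- SpectraSet(wavenumbers(s), 7.3 * X, acquisitionTimes(s))
  expect_equal(intensities(peakNormalize(scaled, 800)),
               intensities(norm1), tolerance = 1e-12)
  expect_equal(intensities(peakNormalize(norm1, 800)),
               intensities(norm1), tolerance = 1e-12)
})

test_that("normalization divides by the windowed maximum", {
  w <- seq(1000, 600, by = -10)
  y <- rep(1, length(w)); y[w == 800] <- 5
  s <- Spectrum(w, y)
  out <- peakNormalize(s, 800, halfwidth = 10)
  expect_equal(intensities(out), y / 5)
})

test_that("the peak is located within the window, not at the anchor channel", {
  w <- seq(1000, 600, by = -2)
  y <- 0.1 + exp(-(w - 802)^2 / (2 * 6^2))
  out <- peakNormalize(Spectrum(w, y), 800, halfwidth = 10)
  # independent argmax within the window
  win <- which(abs(w - 800) <= 10)
  expect_equal(w[win[which.max(y[win])]], 802)
  expect_equal(intensities(out)[w == 802], 1, tolerance = 1e-12)
})

test_that("non-positive window maxima raise a normalization error", {
  w <- seq(1000, 600, by = -10)
  expect_error(peakNormalize(Spectrum(w, rep(-1, length(w))), 800),
               "normalization error")
  expect_error(peakNormalize(Spectrum(w, rep(1, length(w))), 2000),
               "does not overlap")
})

test_that("EMSC of the reference itself is a fixed point", {
  s <- randomSpectraSet(n = 1, p = 30, seed = 22)
  ref <- Spectrum(wavenumbers(s), intensities(s)[1, ])
  res <- emsc(s, reference = ref, degree = 3)
  expect_equal(res@multiplicative, 1, tolerance = 1e-10)
  expect_true(all(abs(res@additive) < 1e-9))
  expect_equal(intensities(res@corrected)[1, ], intensities(ref),
               tolerance = 1e-9)
})

test_that("an exact model match is decomposed exactly", {
  w <- seq(1500, 900, by = -10)
  refY <- exp(-(w - 1200)^2 / (2 * 50^2))
  ref <- Spectrum(w, refY)
  s <- SpectraSet(w, matrix(2 * refY + 3, 1), times = 0)
  res <- emsc(s, reference = ref, degree = 2)
  expect_equal(res@multiplicative, 2, tolerance = 1e-10)
  expect_equal(res@additive[1, 1], 3, tolerance = 1e-9)   # constant term
  expect_true(all(abs(res@additive[1, -1]) < 1e-9))
  expect_equal(intensities(res@corrected)[1, ], refY, tolerance = 1e-9)
})

test_that("EMSC coefficients equal the normal-equations solution", {
  set.seed(23)
  w <- seq(1500, 900, length.out = 20)
  refY <- exp(-(w - 1200)^2 / (2 * 60^2)) + 0.2
  X <- t(replicate(6, runif(1, 0.5, 2) * refY + rnorm(20, 0, 0.1)))
  s <- SpectraSet(w, X, times = 0:5)
  res <- emsc(s, reference = Spectrum(w, refY), degree = 2)
  # independent oracle: solve the normal equations per spectrum
  P <- RamanPAT:::.legendreBasis(wavenumbers(s), 2)
  D <- cbind(refY, P)
  for (i in 1:6) {
    beta <- solve(crossprod(D), crossprod(D, intensities(s)[i, ]))
    expect_equal(res@multiplicative[i], beta[1], tolerance = 1e-8)
    expect_equal(res@additive[i, ], beta[-1], tolerance = 1e-8,
                 ignore_attr = TRUE)
    resid <- intensities(s)[i, ] - D %*% beta
    expect_true(all(abs(crossprod(D, resid)) <=
                      1e-8 * sqrt(colSums(D^2)) * sqrt(sum(resid^2)) + 1e-10))
  }
})

test_that("degenerate multiplicative factors are flagged per spectrum", {
  w <- seq(1500, 900, length.out = 15)
  refY <- sin(w / 100) + 2
  X <- rbind(refY, rep(1, 15))  # second spectrum has no reference component
  s <- SpectraSet(w, X, times = 0:1)
  expect_error(emsc(s, reference = Spectrum(w, refY), degree = 0),
               "spectrum 2")
})
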