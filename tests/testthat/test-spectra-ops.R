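test_that("resampling onto the source axis is the identity", {
  s <- randomSpectraSet(n = 3, p = 25, seed = 2)
  s2 <- resampleToGrid(s, wavenumbers(s))
  expect_equal(intensities(s2), intensities(s), tolerance = 1e-12)
})

test_that("linear ramps resample exactly at half-spacing midpoints", {
  w <- seq(1000, 900, by = -10)
  X <- rbind(seq_along(w) * 2, seq_along(w) * -1 + 30)
  s <- SpectraSet(w, X, times = c(0, 1))
  half <- seq(1000, 900, by = -5)
  s2 <- resampleToGrid(s, half)
  # midpoints of a linear signal are exact averages of the neighbours
  mid <- s2@intensities[, seq(2, length(half) - 1, by = 2)]
  expected <- (X[, -ncol(X)] + X[, -1]) / 2
  expect_equal(mid, expected, tolerance = 1e-12)
})

test_that("resampling outside the source span is a range error", {
  s <- randomSpectraSet(n = 2, p = 20, seed = 3, wmax = 2000, wmin = 600)
  expect_error(resampleToGrid(s, seq(2100, 600, by = -50)), "range error")
})

test_that("region truncation keeps exactly the in-region channels", {
  w <- seq(4000, 400, by = -2)
  s <- SpectraSet(w, matrix(seq_along(w), 1), times = 0)
  r <- RegionSet(c(3050, 2500), c(1800, 650))
  # independent count by scanning the axis
  expected <- sum(w <= 3050 & w >= 2500) + sum(w <= 1800 & w >= 650)
  expect_equal(expected, 276L + 576L)
  s2 <- truncateRegions(s, r)
  expect_equal(nChannels(s2), 852L)
  expect_true(all(diff(wavenumbers(s2)) < 0))
  # idempotence
  s3 <- truncateRegions(s2, r)
  expect_identical(intensities(s3), intensities(s2))
})

test_that("truncation with a full-span region is the channel identity", {
  s <- randomSpectraSet(n = 2, p = 30, seed = 4)
  r <- RegionSet(c(max(wavenumbers(s)), min(wavenumbers(s))))
  expect_equal(intensities(truncateRegions(s, r)), intensities(s))
})

test_that("empty regions are validation errors naming the region", {
  s <- SpectraSet(seq(1800, 650, by = -2),
                  matrix(1, 1, length(seq(1800, 650, by = -2))), times = 0)
  expect_error(truncateRegions(s, RegionSet(c(100, 50))), "\\[100, 50\\]")
})

test_that("nearest-policy alignment picks the exact hit and breaks ties early", {
  w <- c(1000, 900, 800)
  times <- seq(0, 8, by = 1 / 3)
  X <- matrix(rep(seq_along(times), each = 3), ncol = 3, byrow = TRUE)
  s <- SpectraSet(w, X, times)
  ref <- ReferenceTable(4, matrix(1, 1, 1, dimnames = list(NULL, "a")),
                        "g/L")
  al <- alignToReference(s, ref, windowH = 0.5, policy = "nearest")
  expect_equal(al$matchedTimes[[1]], 4.0)
  expect_equal(al$X[1, ], X[which(times == 4), ])
  # tie: reference at the midpoint of two spectra -> earlier one wins
  s2 <- SpectraSet(w, X[1:2, ], times = c(3.8, 4.2))
  ref2 <- ReferenceTable(4, matrix(1, 1, 1, dimnames = list(NULL, "a")),
                         "g/L")
  al2 <- alignToReference(s2, ref2, windowH = 0.5, policy = "nearest")
  expect_equal(al2$matchedTimes[[1]], 3.8)
})

test_that("mean-policy alignment equals the direct average of selected rows", {
  w <- c(1000, 900, 800)
  times <- c(3.67, 4.0, 4.33, 6.0)
  X <- matrix(rnorm(12), 4, 3)
  s <- SpectraSet(w, X, times)
  ref <- ReferenceTable(4, matrix(1, 1, 1, dimnames = list(NULL, "a")),
                        "g/L")
  al <- alignToReference(s, ref, windowH = 0.5, policy = "mean")
  expect_equal(al$X[1, ], colMeans(X[1:3, ]), tolerance = 1e-12)
  expect_equal(al$matchedTimes[[1]], times[1:3])
})

test_that("uncovered timepoints raise an alignment error listing them", {
  s <- randomSpectraSet(n = 5, p = 10, seed = 5)
  ref <- ReferenceTable(200, matrix(1, 1, 1, dimnames = list(NULL, "a")),
                        "g/L")
  expect_error(alignToReference(s, ref), "200")
})
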