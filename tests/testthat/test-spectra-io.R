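test_that("wide CSV round-trips a SpectraSet exactly at declared precision", {
  s <- randomSpectraSet(n = 4, p = 30, seed = 11)
  f <- tempfile(fileext = ".csv")
  writeSpectraCSV(s, f, digits = 12)
  s2 <- readSpectraCSV(f)
  expect_equal(wavenumbers(s2), wavenumbers(s), tolerance = 1e-10)
  expect_equal(intensities(s2), intensities(s), tolerance = 1e-10)
  expect_equal(acquisitionTimes(s2), acquisitionTimes(s), tolerance = 1e-10)
})

test_that("toy wide CSV parses with expected shape and times", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,0.0,0.33",
               "1000,1,4", "900,2,5", "800,3,6"), f)
  s <- readSpectraCSV(f)
  expect_equal(dim(intensities(s)), c(2L, 3L))
  expect_equal(acquisitionTimes(s), c(0.0, 0.33))
  expect_equal(intensities(s)[1, ], c(1, 2, 3))
})

test_that("ascending-axis file is flipped to descending consistently", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,1.5", "800,3", "900,2", "1000,1"), f)
  s <- readSpectraCSV(f)
  expect_equal(wavenumbers(s), c(1000, 900, 800))
  expect_equal(intensities(s)[1, ], c(1, 2, 3))
})

test_that("malformed wide CSVs raise informative format errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,0,1", "1000,1,2", "900,3"), f)
  expect_error(readSpectraCSV(f), "row 3")
  writeLines(c("wavenumber_cm-1,0,1", "1000,1,2", "900,,3"), f)
  expect_error(readSpectraCSV(f), "row 2")
  writeLines(c("wavenumber_cm-1,0,0", "1000,1,2", "900,3,4"), f)
  expect_error(readSpectraCSV(f), "duplicate")
  writeLines(c("wavenumber_cm-1,0,1", "1000,1,2", "1100,3,4",
               "900,5,6"), f)
  expect_error(readSpectraCSV(f), "monotonic")
})

test_that("reference table CSV round-trips, including missing values", {
  v <- matrix(c(52.2, 30.1, 0.5, 1.2, NA, 18.3), 3, 2,
              dimnames = list(NULL, c("glucose", "cdw")))
  ref <- ReferenceTable(c(4, 48, 120), v, units = c("g/L", "g/L"))
  f <- tempfile(fileext = ".csv")
  writeReferenceCSV(ref, f)
  ref2 <- readReferenceCSV(f)
  expect_equal(timepoints(ref2), timepoints(ref))
  expect_equal(referenceValues(ref2), referenceValues(ref),
               tolerance = 1e-9)
  expect_equal(unname(analyteUnits(ref2)["cdw"]), "g/L")
})

test_that("JCAMP reader parses a minimal XYPOINTS block", {
  f <- tempfile(fileext = ".jdx")
  writeJcampFixture(f, x = c(1000, 1002, 1004, 1006, 1008),
                    y = c(1, 2, 3, 2, 1))
  s <- readJCAMP(f)
  expect_s4_class(s, "Spectrum")
  expect_equal(nChannels(s), 5L)
  expect_equal(wavenumbers(s), c(1008, 1006, 1004, 1002, 1000))
  expect_equal(intensities(s), c(1, 2, 3, 2, 1))
})

test_that("JCAMP XFACTOR scales x values and leaves intensities alone", {
  f <- tempfile(fileext = ".jdx")
  writeJcampFixture(f, x = c(500, 501, 502, 503, 504), y = 1:5,
                    xfactor = 2)
  s <- readJCAMP(f)
  expect_equal(sort(wavenumbers(s)), c(1000, 1002, 1004, 1006, 1008))
  expect_equal(sort(intensities(s)), as.numeric(1:5))
})

test_that("JCAMP structural violations are rejected", {
  f <- tempfile(fileext = ".jdx")
  writeJcampFixture(f, x = c(1000, 1002, 1004), y = c(1, 2, 3), npoints = 5)
  expect_error(readJCAMP(f), "NPOINTS")
  writeLines(c("##TITLE=a", "##NPOINTS=2", "##XYPOINTS=(XY..XY)",
               "1, 1", "2, 2", "##END=",
               "##TITLE=b", "##NPOINTS=2", "##XYPOINTS=(XY..XY)",
               "1, 1", "2, 2", "##END="), f)
  expect_error(readJCAMP(f), "multi-block")
  writeLines(c("##TITLE=a", "##NPOINTS=2", "1, 1", "2, 2", "##END="), f)
  expect_error(readJCAMP(f), "XYDATA or ##XYPOINTS")
})

test_that("JCAMP micrometer axes are converted to wavenumbers", {
  f <- tempfile(fileext = ".jdx")
  writeJcampFixture(f, x = c(2.5, 5, 10), y = c(1, 2, 3),
                    xunits = "MICROMETERS")
  s <- readJCAMP(f)
  expect_equal(sort(wavenumbers(s)), c(1000, 2000, 4000))
})
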