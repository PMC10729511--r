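test_that("one component fits an exact rank-1 relationship perfectly", {
  set.seed(41)
  t <- rnorm(10)
  X <- outer(t, c(1, -0.5, 2, 0.3))   # rank-1 X block
  y <- 3 * X[, 1]
  m <- plsrFit(X, y, 1)
  yhat <- plsrPredict(m, X)
  expect_equal(rSquared(y, yhat), 1, tolerance = 1e-10)
  expect_equal(yhat, y, tolerance = 1e-8)
})

test_that("full-rank PLSR equals ordinary least squares", {
  set.seed(42)
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  m <- plsrFit(X, y, 3)
  # OLS oracle on centered data
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  bOls <- as.numeric(solve(crossprod(Xc), crossprod(Xc, yc)))
  expect_equal(m@coefficients, bOls, tolerance = 1e-8)
  expect_equal(plsrPredict(m, X),
               mean(y) + as.numeric(Xc %*% bOls), tolerance = 1e-8)
})

test_that("score vectors are mutually orthogonal", {
  set.seed(43)
  X <- matrix(rnorm(200), 10, 20)
  y <- rnorm(10)
  fit <- RamanPAT:::.nipalsPls1(X, y, 5)
  G <- crossprod(fit$T)
  nrm <- sqrt(diag(G))
  off <- abs(G) / outer(nrm, nrm)
  diag(off) <- 0
  expect_true(all(off <= 1e-8))
})

test_that("training residual is non-increasing in the component count", {
  set.seed(44)
  X <- matrix(rnorm(120), 8, 15)
  y <- rnorm(8)
  res <- vapply(1:6, function(a) {
    m <- plsrFit(X, y, a)
    rmse(y, plsrPredict(m, X))
  }, 0)
  expect_true(all(diff(res) <= 1e-10))
})

test_that("prediction identities hold", {
  set.seed(45)
  X <- matrix(rnorm(60), 6, 10)
  y <- rnorm(6)
  m <- plsrFit(X, y, 2)
  # predicting the centering vector returns the response mean
  expect_equal(plsrPredict(m, m@xMean), mean(y), tolerance = 1e-10)
  # row permutation equivariance
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_equal(plsrPredict(m, X[perm, ]), plsrPredict(m, X)[perm])
  # channel mismatch
  expect_error(plsrPredict(m, X[, 1:5]), "shape error")
})

test_that("adding a constant to every spectrum leaves predictions unchanged", {
  set.seed(46)
  X <- matrix(rnorm(80), 8, 10)
  y <- rnorm(8)
  m1 <- plsrFit(X, y, 3)
  m2 <- plsrFit(X + 5, y, 3)
  Xnew <- matrix(rnorm(30), 3, 10)
  expect_equal(plsrPredict(m1, Xnew), plsrPredict(m2, Xnew + 5),
               tolerance = 1e-8)
})

test_that("requesting more components than the rank is an error", {
  X <- cbind(1:6, (1:6) * 2, (1:6) * 3)   # rank 1 after centering
  expect_error(plsrFit(X, rnorm(6), 2), "rank error")
  expect_error(plsrFit(matrix(rnorm(24), 6, 4), rep(2, 6), 2),
               "degenerate error")
})

test_that("LOO-CV matches the brute-force n-refit oracle exactly", {
  set.seed(47)
  X <- matrix(rnorm(8 * 6), 8, 6)
  y <- X[, 1] - 2 * X[, 3] + rnorm(8, 0, 0.1)
  cv <- looCv(X, y, 4)
  oracle <- bruteLooCv(X, y, 4)
  expect_equal(cv$rmse, oracle$rmse, tolerance = 1e-10)
  expect_equal(cv$r2, oracle$r2, tolerance = 1e-10)
})

test_that("a noiseless linear response is recovered with one component", {
  set.seed(48)
  # one informative direction: the other channels are scaled copies of it,
  # so a single latent variable carries all the signal
  t <- rnorm(10)
  X <- outer(t, c(0.2, 1, -0.7, 0.5, 2))
  y <- 2 + 0.5 * X[, 2]
  cv <- looCv(X, y, 3)
  expect_lt(cv$rmse[1], 1e-8)
  expect_equal(selectComponents(cv$rmse), 1L)
})

test_that("CV R^2 can be negative for adversarial responses", {
  # response orthogonal to the predictors: held-out predictions are worse
  # than the mean
  set.seed(49)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- c(1, -1, 1, -1, 1, -1, 1, -1) + rnorm(8, 0, 1e-6)
  cv <- looCv(X, y, 2)
  sse <- colSums((cv$predictions - y)^2)
  expect_equal(cv$r2, 1 - sse / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_true(any(cv$r2 < 0))
})

test_that("component selection optimizes RMSE with parsimony tie-break", {
  expect_equal(selectComponents(c(5.0, 2.0, 2.5)), 2L)
  expect_equal(selectComponents(c(2.0, 2.0, 3.0)), 1L)
  expect_equal(selectComponents(c(4, 3, 2, 1)), 4L)
  expect_error(selectComponents(numeric()), "empty")
})

test_that("LOO-CV input contracts are enforced", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(looCv(X, rnorm(4), 3), "Amax")
  expect_error(looCv(X[1:2, ], rnorm(2), 1), "n >= 3")
  expect_error(looCv(X, c(1, 1, 1, 2), 1), "fold 4")
})

test_that("calibration models survive a JSON round-trip", {
  set.seed(50)
  X <- matrix(rnorm(60), 6, 10)
  y <- rnorm(6) + 3
  m <- plsrFit(X, y, 2, analyte = "glucose", units = "g/L",
               recipe = builtinRecipe("online_emsc_d4"),
               wavenumbers = seq(1000, 910, by = -10),
               cvRmse = c(1, 0.5), cvR2 = c(0.8, 0.9))
  f <- tempfile(fileext = ".json")
  writeCalibrationModel(m, f, trainingHash = "abc")
  m2 <- readCalibrationModel(f)
  expect_equal(m2@coefficients, m@coefficients, tolerance = 1e-12)
  expect_equal(m2@xMean, m@xMean, tolerance = 1e-12)
  expect_equal(plsrPredict(m2, X), plsrPredict(m, X), tolerance = 1e-12)
  expect_equal(m2@A, m@A)
  expect_equal(recipeSteps(m2@recipe), recipeSteps(m@recipe))
  expect_equal(m2@cvRmse, m@cvRmse)
})
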