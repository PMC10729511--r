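# Shared fixtures and independent oracles for the test suite.

# A smooth-ish random SpectraSet on a descending axis.
randomSpectraSet <- function(n = 5, p = 40, seed = 1, wmax = 2000,
                             wmin = 600) {
  set.seed(seed)
  w <- seq(wmax, wmin, length.out = p)
  X <- t(replicate(n, {
    peaks <- runif(3, wmin, wmax)
    rowSums(sapply(peaks, function(c0)
      runif(1, 0.5, 2) * exp(-(w - c0)^2 / (2 * runif(1, 20, 80)^2)))) +
      rnorm(p, 0, 0.02)
  }))
  SpectraSet(w, X, times = seq(0, by = 1 / 3, length.out = n))
}

# O(n^2) lower-convex-hull baseline oracle: the hull at x is the minimum
# over all chords between data points spanning x (and the points themselves).
bruteHullBaseline <- function(x, y) {
  n <- length(x)
  base <- y
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sel <- which(x >= x[i] & x <= x[j])
    yl <- y[i] + (y[j] - y[i]) * (x[sel] - x[i]) / (x[j] - x[i])
    base[sel] <- pmin(base[sel], yl)
  }
  base
}

# brute-force one-sample-out CV: refits a separate PLS model per fold and
# per candidate A via the public fitting interface.
bruteLooCv <- function(X, y, Amax) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, Amax)
  for (a in seq_len(Amax)) for (i in seq_len(n)) {
    m <- plsrFit(X[-i, , drop = FALSE], y[-i], a)
    pred[i, a] <- plsrPredict(m, X[i, ])
  }
  sse <- colSums((pred - y)^2)
  list(rmse = sqrt(sse / n), r2 = 1 - sse / sum((y - mean(y))^2))
}

# minimal JCAMP-DX writer for fixture files
writeJcampFixture <- function(path, x, y, xfactor = 1, yfactor = 1,
                              npoints = length(x), xunits = "1/CM") {
  lines <- c(
    "##TITLE=synthetic fixture",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    paste0("##XUNITS=", xunits),
    "##YUNITS=ARBITRARY UNITS",
    paste0("##XFACTOR=", xfactor),
    paste0("##YFACTOR=", yfactor),
    paste0("##FIRSTX=", x[1] * xfactor),
    paste0("##LASTX=", x[length(x)] * xfactor),
    paste0("##NPOINTS=", npoints),
    "##XYPOINTS=(XY..XY)",
    paste(x, y, sep = ", "),
    "##END=")
  writeLines(lines, path)
  path
}
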