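#' Principal component analysis of preprocessed spectra
#'
#' Mean-centered PCA via singular value decomposition. Loadings are
#' orthonormal; explained-variance fractions are non-increasing and sum to
#' at most 1. Sign convention: each loading vector is flipped so its
#' largest-magnitude element is positive (scores flip with it).
#'
#' @param X numeric matrix [n x p] (rows = samples) or a
#'   \linkS4class{SpectraSet}.
#' @param k number of components, at most min(n-1, p).
#' @return List with \code{scores} [n x k], \code{loadings} [p x k] and
#'   \code{explained} (variance fractions, length k).
#' @export
pcaSpectra <- function(X, k) {
  if (is(X, "SpectraSet")) X <- intensities(X)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(k)
  if (k > min(n - 1L, p))
    stop(sprintf("rank error: k = %d exceeds min(n-1, p) = %d",
                 k, min(n - 1L, p)))
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Pearson correlation matrix of reference analytes
#'
#' Pairwise-complete Pearson correlations between the analytes of a
#' reference table (or the columns of a matrix). Cells with fewer than 3
#' complete pairs or a zero-variance series are NA and flagged with a
#' warning rather than silently set to 0.
#'
#' @param ref a \linkS4class{ReferenceTable} or numeric matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(ref) {
  v <- if (is(ref, "ReferenceTable")) ref@values else as.matrix(ref)
  k <- ncol(v)
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(v[, i], v[, j])
    if (sum(ok) < 3L && i != j) r[i, j] <- NA_real_
  }
  diag(r) <- ifelse(apply(v, 2L, function(x)
    stats::var(x, na.rm = TRUE)) > 0, 1, NA_real_)
  if (anyNA(r))
    warning("undefined correlation entries (zero variance or < 3 complete pairs) flagged as NA")
  r
}
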