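# Shared fixtures, built once per test run and cached: OpenBabel
# fingerprinting dominates test runtime, so libraries and fingerprint
# matrices are reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

fix_library <- function(n, mode = "congeneric", seed = 7) {
  cached(sprintf("lib_%s_%d_%d", mode, n, seed), function()
    as_chem_library(generate_library(n, mode, seed = seed)))
}

fix_fps <- function(n, mode = "congeneric", fp_type = "ecfp4", seed = 7) {
  cached(sprintf("fps_%s_%d_%d_%s", mode, n, seed, fp_type), function()
    library_fingerprints(fix_library(n, mode, seed), fp_type))
}

# A tiny hand-picked toy library: three near-identical ethanol homologues
# plus three unrelated molecules.  Used where chemistry must be obvious.
toy_smiles <- c("CCO", "CCCO", "CCCCO",
                "c1ccccc1", "c1ccc2ccccc2c1", "CC(=O)Nc1ccc(O)cc1")

fix_toy <- function() cached("toy", function() as_chem_library(toy_smiles))

# Independent brute-force PCA oracle: eigendecomposition of the sample
# covariance matrix.  Kept deliberately separate from the SVD path it checks.
oracle_pca_scores <- function(m, n_pcs) {
  xc <- sweep(m, 2L, colMeans(m))
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  p <- min(n_pcs, ncol(m), sum(ev$values > 1e-12 * max(ev$values, 0)))
  xc %*% ev$vectors[, seq_len(p), drop = FALSE]
}

# Independent all-pairs double-loop distance oracle.
oracle_distances <- function(scores) {
  n <- nrow(scores)
  out <- numeric(0)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      out <- c(out, sqrt(sum((scores[i, ] - scores[j, ])^2)))
  out
}

# Compare score matrices column-by-column up to sign.
expect_scores_equal <- function(a, b, tol = 1e-9) {
  expect_equal(ncol(a), ncol(b))
  for (j in seq_len(ncol(a))) {
    d <- min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
    expect_lt(d, tol)
  }
}

# A seeded random orthogonal matrix (QR of a Gaussian matrix).
random_orthogonal <- function(p, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * p), p, p)))
}
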