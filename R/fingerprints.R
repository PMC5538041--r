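# Fingerprints, Tanimoto similarity, and the N x k compound-vs-satellite
# similarity matrix at the heart of the satellite map.
#
# MACCS keys are the fixed 166-bit structural-key dictionary.  "ECFP4" is the
# community-standard extended-connectivity fingerprint of diameter 4
# (radius-2 atom neighborhoods); some toolkits label the same fingerprint
# "radius 4".  The toolkit produces ECFP4 at 4096 bits; it is OR-folded in
# halves down to `n_bits` (default 2048), the usual hashed representation.

MACCS_LEN <- 166L
OB_ECFP_LEN <- 4096L

# 0/1 fingerprint matrix (rows = molecules) computed straight from SMILES.
ob_fp_matrix <- function(smiles, fp_type, n_bits) {
  name <- switch(fp_type, maccs = "MACCS", ecfp4 = "ECFP4")
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  m <- suppressWarnings(ChemmineOB::fingerprint_OB(mols, name))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  storage.mode(m) <- "integer"
  if (fp_type == "maccs") {
    if (ncol(m) > MACCS_LEN && any(m[, (MACCS_LEN + 1L):ncol(m)] != 0L))
      satmap_error("MACCS fingerprint has bits beyond key 166")
    m <- m[, seq_len(MACCS_LEN), drop = FALSE]
  } else {
    if (n_bits > ncol(m) || ncol(m) %% n_bits != 0L)
      satmap_error(sprintf("n_bits must divide %d", ncol(m)))
    while (ncol(m) > n_bits) {
      half <- ncol(m) / 2L
      m <- (m[, seq_len(half), drop = FALSE] |
              m[, half + seq_len(half), drop = FALSE]) * 1L
    }
  }
  m
}

check_fp_args <- function(fp_type, n_bits) {
  if (fp_type == "ecfp4" && n_bits < 64L)
    satmap_error("n_bits must be at least 64")
}

#' Fingerprint every molecule of a library
#'
#' Computes one fingerprint per molecule, once; all similarity matrices are
#' then built from this cached bit matrix, so growing a satellite set never
#' refingerprints anything.
#'
#' @param library a `chem_library`.
#' @param fp_type `"ecfp4"` (circular, diameter 4, hashed) or `"maccs"`
#'   (166 structural keys).
#' @param n_bits hashed fingerprint length for ECFP4 (ignored for MACCS);
#'   must be a power-of-two divisor of 4096, at least 64.
#' @return An `fp_matrix`: a 0/1 integer matrix with one row per molecule
#'   (rownames = ids) and attributes `fp_type` and `n_bits`.
#' @export
library_fingerprints <- function(library, fp_type = c("ecfp4", "maccs"),
                                 n_bits = 2048L) {
  fp_type <- match.arg(fp_type)
  check_fp_args(fp_type, n_bits)
  m <- ob_fp_matrix(library$smiles, fp_type, n_bits)
  rownames(m) <- library$id
  structure(m, fp_type = fp_type, n_bits = ncol(m), class = "fp_matrix")
}

#' Fingerprint a single molecule
#'
#' @param x a SMILES string or a single-molecule `chem_library`.
#' @inheritParams library_fingerprints
#' @return A `fingerprint`: sorted integer positions of the set bits, with
#'   attributes `length` (total bit count: 166 for MACCS, `n_bits` for ECFP4)
#'   and `fp_type`.  Identical canonical SMILES give identical fingerprints.
#' @export
fingerprint <- function(x, fp_type = c("ecfp4", "maccs"), n_bits = 2048L) {
  fp_type <- match.arg(fp_type)
  if (is.character(x)) x <- as_chem_library(x)
  fps <- library_fingerprints(x, fp_type, n_bits)
  as_fingerprint(fps, 1L)
}

#' Extract one fingerprint from an `fp_matrix`
#' @param fps an `fp_matrix` from [library_fingerprints()].
#' @param i row index.
#' @return A `fingerprint` object.
#' @export
as_fingerprint <- function(fps, i) {
  structure(which(fps[i, ] != 0L),
            length = ncol(fps), fp_type = attr(fps, "fp_type"),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s, %d/%d bits set>\n",
              attr(x, "fp_type"), length(unclass(x)), attr(x, "length")))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits.  Two empty fingerprints
#' have similarity 0 by convention.
#'
#' @param a,b `fingerprint` objects of the same type and length.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!identical(attr(a, "fp_type"), attr(b, "fp_type")) ||
      !identical(attr(a, "length"), attr(b, "length")))
    satmap_error("fingerprints have mismatched type or length")
  ab <- unclass(a); bb <- unclass(b)
  u <- length(union(ab, bb))
  if (u == 0L) return(0)
  length(intersect(ab, bb)) / u
}

# Tanimoto of every row of `fps` against the rows indexed by `cols`.
# crossprod on the 0/1 matrix gives the intersection counts in one BLAS call.
tanimoto_cross <- function(fps, cols) {
  fm <- unclass(fps)
  inter <- fm %*% t(fm[cols, , drop = FALSE])
  ones <- rowSums(fm)
  uni <- outer(ones, ones[cols], "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(rownames(fm), rownames(fm)[cols])
  sim
}

#' Compound-versus-satellite similarity matrix
#'
#' The N x k matrix whose entry (i, j) is the Tanimoto similarity between
#' compound i and satellite j.  Rows cover all N compounds, satellites
#' included, so the entry of a compound against itself is exactly 1.  With
#' satellites = the full library the result is the symmetric N x N pairwise
#' matrix (the gold-standard input).
#'
#' @param fps an `fp_matrix` from [library_fingerprints()].
#' @param satellites a `satellite_set` or an integer vector of unique
#'   1-based row indices.
#' @return A `similarity_matrix`: numeric N x k matrix with attributes
#'   `sat_indices` and `fp_type`; all entries in `[0, 1]`.
#' @export
similarity_matrix <- function(fps, satellites) {
  idx <- if (inherits(satellites, "satellite_set")) satellites$indices
         else as.integer(satellites)
  if (length(idx) == 0L) satmap_error("satellite set is empty")
  if (anyDuplicated(idx)) satmap_error("duplicate satellite indices")
  if (any(idx < 1L | idx > nrow(fps)))
    satmap_error("satellite index out of range")
  sim <- tanimoto_cross(fps, idx)
  structure(sim, sat_indices = idx, fp_type = attr(fps, "fp_type"),
            class = c("similarity_matrix", "matrix"))
}

#' Median pairwise similarity of a library (internal 2D diversity)
#'
#' The median Tanimoto similarity over all N(N-1)/2 unordered distinct pairs,
#' self-pairs excluded.  A smaller median means a more diverse library: a
#' congeneric series sits high (0.6-0.8 with MACCS), a mixed-scaffold
#' collection low (below 0.5).
#'
#' @param x a `chem_library` or an `fp_matrix`.
#' @inheritParams library_fingerprints
#' @return The median similarity, a number in `[0, 1]`.
#' @export
median_pairwise_similarity <- function(x, fp_type = c("ecfp4", "maccs"),
                                       n_bits = 2048L) {
  fps <- if (inherits(x, "fp_matrix")) x
         else library_fingerprints(x, match.arg(fp_type), n_bits)
  n <- nrow(fps)
  if (n < 2L) satmap_error("need at least 2 molecules")
  sim <- tanimoto_cross(fps, seq_len(n))
  stats::median(sim[upper.tri(sim)])
}
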