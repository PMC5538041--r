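# PCA of the similarity matrix, condensed pairwise distances, and the
# distance-correlation fidelity metric against the full-matrix gold standard.

#' PCA projection of a similarity matrix
#'
#' Columns are mean-centered (no variance scaling: every feature is a
#' Tanimoto similarity on the common `[0, 1]` scale) and the data are
#' projected onto the top right singular directions, computed by SVD.  The
#' effective number of components is `min(n_pcs, k, rank)` — with a single
#' satellite only one PC exists.  Each component's sign is fixed so its
#' largest-magnitude loading is positive; signs are immaterial to distances.
#'
#' @param m a `similarity_matrix` (or any numeric N x k matrix).
#' @param n_pcs number of principal components requested (1, 2 or 3).
#' @return A `projection_result`: list with `scores` (N x p), the
#'   non-increasing `explained_variance_ratio` (fractions of total variance,
#'   summing to at most 1), `n_pcs_requested`, `n_pcs_effective`, and the
#'   column `centers` and `rotation` needed to project new compounds.
#' @section Errors: an all-rows-identical (zero variance) matrix raises a
#'   degenerate-geometry error rather than returning NaN scores.
#' @export
pca_project <- function(m, n_pcs = 2L) {
  m <- unclass(m)
  if (is.null(dim(m)) || nrow(m) == 0L || ncol(m) == 0L)
    satmap_error("empty similarity matrix")
  if (n_pcs < 1L) satmap_error("n_pcs must be >= 1")
  centers <- colMeans(m)
  xc <- sweep(m, 2L, centers)
  sv <- svd(xc)
  if (sv$d[1] <= 0 || !is.finite(sv$d[1]))
    degenerate_geometry_error(
      "similarity matrix has zero variance (all compounds identical?)")
  rank <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  if (rank == 0L)
    degenerate_geometry_error("similarity matrix has zero variance")
  p <- min(as.integer(n_pcs), ncol(m), rank)
  rot <- sv$v[, seq_len(p), drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- xc %*% rot
  colnames(scores) <- paste0("PC", seq_len(p))
  rownames(scores) <- rownames(m)
  evr <- (sv$d^2 / sum(sv$d^2))[seq_len(p)]
  structure(list(scores = scores,
                 explained_variance_ratio = evr,
                 n_pcs_requested = as.integer(n_pcs),
                 n_pcs_effective = p,
                 centers = centers, rotation = rot),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("PCA projection: %d compounds, %d PC(s) (requested %d)\n",
              nrow(x$scores), x$n_pcs_effective, x$n_pcs_requested))
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "), "\n")
  invisible(x)
}

#' Condensed pairwise Euclidean distances
#'
#' Euclidean distance in PC-score space for every unordered compound pair, in
#' the fixed condensed order (1,2), (1,3), ..., (1,N), (2,3), ...
#'
#' @param projection a `projection_result` or a numeric score matrix.
#' @return A `distance_vector`: numeric vector of length N(N-1)/2 with
#'   attribute `n`.
#' @export
pairwise_distances <- function(projection) {
  scores <- if (inherits(projection, "projection_result")) projection$scores
            else as.matrix(projection)
  n <- nrow(scores)
  if (n < 2L) satmap_error("need at least 2 compounds for pairwise distances")
  structure(as.vector(stats::dist(scores)), n = n, class = "distance_vector")
}

#' Correlation between two condensed distance vectors
#'
#' The map-fidelity metric: the Pearson product-moment correlation between
#' the pairwise distances of two embeddings of the same N compounds.
#' Spearman rank correlation is available as an option.
#'
#' @param a,b `distance_vector`s over the same N compounds.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A number in `[-1, 1]`.
#' @section Errors: a constant distance vector (all compounds coincident)
#'   raises a degenerate-geometry error — the correlation is undefined.
#' @export
distance_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  na <- attr(a, "n") %||% NA_integer_
  nb <- attr(b, "n") %||% NA_integer_
  if (!is.na(na) && !is.na(nb) && na != nb)
    satmap_error("distance vectors cover different compound counts")
  if (length(a) != length(b))
    satmap_error("distance vectors have different lengths")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    degenerate_geometry_error("constant distance vector: correlation undefined")
  stats::cor(as.numeric(a), as.numeric(b), method = method)
}

#' Gold-standard projection and distances
#'
#' The reference every satellite map is judged against: PCA of the full
#' N x N similarity matrix, reduced to the same 2 or 3 components used for
#' visualization (not the full-dimensional distances), and its condensed
#' pairwise distances.
#'
#' @param x a `chem_library` or an `fp_matrix`.
#' @inheritParams library_fingerprints
#' @param n_pcs number of principal components (2 or 3).
#' @return A list with `projection` (a `projection_result`) and `distances`
#'   (a `distance_vector`).
#' @export
gold_standard <- function(x, fp_type = c("ecfp4", "maccs"), n_pcs = 2L,
                          n_bits = 2048L) {
  fps <- if (inherits(x, "fp_matrix")) x
         else library_fingerprints(x, match.arg(fp_type), n_bits)
  if (nrow(fps) < 2L) satmap_error("need at least 2 molecules")
  sim <- similarity_matrix(fps, seq_len(nrow(fps)))
  proj <- pca_project(sim, n_pcs)
  list(projection = proj, distances = pairwise_distances(proj))
}
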