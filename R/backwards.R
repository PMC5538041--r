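# The backwards (validation) experiment: sweep the satellite count from 1 to
# N-1 and trace the distance correlation against the full-matrix gold
# standard, repeated with independent seeds.

#' Backwards validation sweep
#'
#' For each of `n_repeats` seeded repeats, a full selection sequence of all N
#' compounds is drawn by the configured strategy; for every satellite count
#' k = 1 .. N-1 the first k compounds of that sequence serve as satellites,
#' the N x k similarity matrix is projected, and the pairwise distances are
#' correlated against the gold standard.  The prefix property of the
#' selection sequence means each repeat computes every similarity column
#' exactly once.  Degenerate geometries at small k (e.g. a single satellite
#' equidistant from everything) are recorded as `NA` and the sweep continues.
#'
#' @param library a `chem_library` with at least 3 molecules.
#' @param config a [map_config()]; uses `fp_type`, `n_bits`, `n_pcs`,
#'   `strategy`, `n_repeats` and `base_seed` (repeat r seeds with
#'   `base_seed + r - 1`).
#' @param fps optional precomputed `fp_matrix`.
#' @return A `correlation_curves` data frame with columns `repeat`, `k`,
#'   `fraction` and `r`, and attributes `n` and `config`.
#' @export
backwards_run <- function(library, config = map_config(), fps = NULL) {
  n <- length(library)
  if (n < 3L) satmap_error("need at least 3 molecules")
  if (is.null(fps))
    fps <- library_fingerprints(library, config$fp_type, config$n_bits)
  gs <- gold_standard(fps, n_pcs = config$n_pcs)
  out <- vector("list", config$n_repeats)
  for (rep_i in seq_len(config$n_repeats)) {
    seed <- config$base_seed + rep_i - 1L
    seq_set <- select_satellites(fps, n, config$strategy, seed)
    sim_full <- tanimoto_cross(fps, seq_set$indices)  # columns in pick order
    r <- rep(NA_real_, n - 1L)
    for (k in seq_len(n - 1L)) {
      r[k] <- tryCatch({
        proj <- pca_project(sim_full[, seq_len(k), drop = FALSE],
                            config$n_pcs)
        distance_correlation(gs$distances, pairwise_distances(proj))
      }, satmap_degenerate_geometry = function(e) NA_real_)
    }
    out[[rep_i]] <- data.frame(rep_i, k = seq_len(n - 1L),
                               fraction = seq_len(n - 1L) / n, r = r)
  }
  res <- do.call(rbind, out)
  names(res)[1] <- "repeat"
  structure(res, n = n, config = config,
            class = c("correlation_curves", "data.frame"))
}

#' Smallest satellite fraction sustaining a correlation threshold
#'
#' The smallest k/N such that the curve stays at or above `threshold` for
#' every k' >= k (a sustained crossing — a single touch followed by a dip
#' does not count).  Returns 1.0 when the threshold is never sustained.
#' Missing correlations (degenerate small-k geometries) are excluded before
#' scanning.
#'
#' @param curve a single repeat's curve: a data frame with columns `k` and
#'   `r` (e.g. one `repeat` of a [backwards_run()] result).
#' @param threshold correlation threshold (default 0.9).
#' @param n library size N; taken from the curve's `n` attribute if absent.
#' @return A fraction in `(0, 1]`.
#' @export
satellites_fraction_for_threshold <- function(curve, threshold = 0.9,
                                              n = attr(curve, "n")) {
  if (is.null(n)) satmap_error("library size n is required")
  if ("repeat" %in% names(curve) && length(unique(curve[["repeat"]])) > 1L)
    satmap_error("pass a single repeat's curve")
  keep <- !is.na(curve$r)
  k <- curve$k[keep]; r <- curve$r[keep]
  if (length(r) == 0L) return(1.0)
  bad <- which(r < threshold)
  if (length(bad) == 0L) return(k[1] / n)
  last_bad <- max(bad)
  if (last_bad == length(r)) return(1.0)
  k[last_bad + 1L] / n
}

#' @export
plot.correlation_curves <- function(x, threshold = 0.9, ...) {
  reps <- unique(x[["repeat"]])
  cols <- grDevices::hcl.colors(max(length(reps), 2L), "Dark 3")
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(min(0, min(x$r, na.rm = TRUE)), 1),
                 xlab = "satellite fraction k/N",
                 ylab = "distance correlation vs gold standard",
                 main = "Backwards validation", ...)
  for (i in seq_along(reps)) {
    cur <- x[x[["repeat"]] == reps[i], ]
    graphics::lines(cur$fraction, cur$r, col = cols[i])
  }
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(x)
}
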