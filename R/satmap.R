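# The forward (production) procedure: fit a chemical space map from a
# growing satellite set, stopping when consecutive stages agree.

#' Run configuration for satellite map procedures
#'
#' Bundles the tunable parameters shared by [satmap()], [backwards_run()] and
#' [benchmark_map()].
#'
#' @param fp_type fingerprint type, `"ecfp4"` or `"maccs"`.
#' @param n_bits hashed ECFP4 length (ignored for MACCS).
#' @param n_pcs number of principal components for the map (2 or 3; the
#'   2-PC map is the recommended default).
#' @param strategy satellite selection strategy, `"random"` or `"maxmin"`;
#'   random selection is the more stable default.
#' @param start_fraction fraction of the library used as the initial
#'   satellite set (default 0.25).
#' @param step_fraction fraction of the library appended per stage
#'   (default 0.05).
#' @param corr_threshold consecutive-stage distance correlation at which the
#'   forward procedure stops (default 0.9).
#' @param n_repeats number of repeated runs in [backwards_run()] (default 5);
#'   repeat r uses seed `base_seed + r - 1`.
#' @param base_seed integer seed.
#' @return A `map_config` list.
#' @export
map_config <- function(fp_type = c("ecfp4", "maccs"), n_bits = 2048L,
                       n_pcs = 2L, strategy = c("random", "maxmin"),
                       start_fraction = 0.25, step_fraction = 0.05,
                       corr_threshold = 0.9, n_repeats = 5L, base_seed = 1L) {
  fp_type <- match.arg(fp_type)
  strategy <- match.arg(strategy)
  if (start_fraction <= 0 || start_fraction > 1)
    satmap_error("start_fraction must be in (0, 1]")
  if (step_fraction <= 0 || step_fraction > 1)
    satmap_error("step_fraction must be in (0, 1]")
  if (corr_threshold <= 0 || corr_threshold > 1)
    satmap_error("corr_threshold must be in (0, 1]")
  if (!n_pcs %in% 1:3) satmap_error("n_pcs must be 1, 2 or 3")
  structure(list(fp_type = fp_type, n_bits = as.integer(n_bits),
                 n_pcs = as.integer(n_pcs), strategy = strategy,
                 start_fraction = start_fraction,
                 step_fraction = step_fraction,
                 corr_threshold = corr_threshold,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed)),
            class = "map_config")
}

select_satellites <- function(fps, k, strategy, seed) {
  if (strategy == "random") select_random(nrow(fps), k, seed)
  else select_maxmin(fps, k, seed)
}

#' Fit a satellite chemical space map
#'
#' Fits a 2- or 3-PC map of a compound library without ever computing the
#' full N x N similarity matrix.  An initial satellite set of
#' `ceiling(start_fraction * N)` compounds is selected; each stage appends
#' `ceiling(step_fraction * N)` more and re-projects all N compounds.  The
#' procedure stops as soon as the pairwise Euclidean distances of consecutive
#' stages correlate at `corr_threshold` or better, or the satellite set
#' saturates at the full library.  It therefore terminates in at most
#' `ceiling((1 - start_fraction) / step_fraction) + 1` stages.  Because grown
#' satellite sets keep the earlier selection as a prefix, similarity columns
#' computed at one stage are reused unchanged at the next.
#'
#' @param library a `chem_library` with at least 3 molecules.
#' @param config a [map_config()].
#' @param validate also compute the full-matrix gold standard and the map's
#'   distance correlation against it (`validation_r`).  Defeats the purpose
#'   for large libraries; meant for benchmarking.
#' @param fps optional precomputed `fp_matrix` (must match the config).
#' @return An object of class `"satmap"`: a list with the final
#'   `projection` (a `projection_result` over all N compounds), `satellites`
#'   (a `satellite_set`), `stages` (data frame of satellite count `k`,
#'   `fraction`, and consecutive-stage correlation `r`, `NA` for the first
#'   stage), `converged`, `saturated`, `validation_r` (if requested),
#'   `config`, and the library ids/smiles.  Methods: `print`, `summary`,
#'   `plot`, `predict`, `coef`.
#' @examples
#' \dontrun{
#' lib <- as_chem_library(generate_library(100, "congeneric", seed = 7))
#' fit <- satmap(lib, map_config(base_seed = 1))
#' summary(fit)
#' plot(fit)
#' }
#' @export
satmap <- function(library, config = map_config(), validate = FALSE,
                   fps = NULL) {
  n <- length(library)
  if (n < 3L) satmap_error("need at least 3 molecules")
  if (is.null(fps))
    fps <- library_fingerprints(library, config$fp_type, config$n_bits)
  k0 <- min(n, ceiling(config$start_fraction * n))
  step <- max(1L, ceiling(config$step_fraction * n))
  sats <- select_satellites(fps, k0, config$strategy, config$base_seed)
  sim <- similarity_matrix(fps, sats)
  proj <- pca_project(sim, config$n_pcs)
  d_prev <- pairwise_distances(proj)
  ks <- length(sats); rs <- NA_real_
  converged <- sats$saturated
  stage <- 1L
  while (!converged) {
    stage <- stage + 1L
    sats <- grow_satellites(sats, fps, step,
                            seed = config$base_seed + 1000L * stage)
    new_idx <- sats$indices[(ncol(sim) + 1L):length(sats)]
    sim2 <- cbind(unclass(sim), tanimoto_cross(fps, new_idx))
    sim <- structure(sim2, sat_indices = sats$indices,
                     fp_type = attr(fps, "fp_type"),
                     class = c("similarity_matrix", "matrix"))
    proj <- pca_project(sim, config$n_pcs)
    d_new <- pairwise_distances(proj)
    r <- distance_correlation(d_prev, d_new)
    ks <- c(ks, length(sats)); rs <- c(rs, r)
    converged <- r >= config$corr_threshold || sats$saturated
    d_prev <- d_new
  }
  fit <- structure(list(
    projection = proj, satellites = sats,
    stages = data.frame(k = ks, fraction = ks / n, r = rs),
    converged = converged, saturated = sats$saturated,
    validation_r = NULL,
    config = config, n = n,
    ids = library$id, smiles = library$smiles,
    sat_fps = unclass(fps)[sats$indices, , drop = FALSE],
    call = match.call()), class = "satmap")
  if (validate) {
    gs <- gold_standard(fps, n_pcs = config$n_pcs)
    fit$validation_r <- distance_correlation(gs$distances, d_prev)
  }
  fit
}

#' @export
print.satmap <- function(x, ...) {
  cat(sprintf("Satellite chemical space map: %d compounds, %d PCs\n",
              x$n, x$projection$n_pcs_effective))
  cat(sprintf("  satellites: %d (%.0f%%), strategy=%s, %d stage(s), %s\n",
              length(x$satellites), 100 * length(x$satellites) / x$n,
              x$config$strategy, nrow(x$stages),
              if (x$converged) "converged" else "not converged"))
  last_r <- utils::tail(stats::na.omit(x$stages$r), 1)
  if (length(last_r))
    cat(sprintf("  final stage-to-stage distance correlation: %.4f\n", last_r))
  if (!is.null(x$validation_r))
    cat(sprintf("  validation vs gold standard: r = %.4f\n", x$validation_r))
  invisible(x)
}

#' @export
summary.satmap <- function(object, ...) {
  structure(list(fit = object), class = "summary.satmap")
}

#' @export
print.summary.satmap <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", f$projection$explained_variance_ratio),
            collapse = ", "), "\n")
  cat("\nStage trace (r = correlation with previous stage):\n")
  print(f$stages, row.names = FALSE)
  invisible(x)
}

#' @export
coef.satmap <- function(object, ...) object$projection$rotation

#' Project compounds onto a fitted satellite map
#'
#' New compounds are placed on the map by computing their Tanimoto
#' similarities to the fitted satellites and applying the stored centering
#' and rotation — no refit.  Called without `newdata` it returns the fitted
#' scores.
#'
#' @param object a fitted `satmap`.
#' @param newdata a `chem_library` or character vector of SMILES.
#' @param ... unused.
#' @return Score matrix with one row per compound.
#' @export
predict.satmap <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$projection$scores)
  if (is.character(newdata)) newdata <- as_chem_library(newdata)
  fps <- library_fingerprints(newdata, object$config$fp_type,
                              object$config$n_bits)
  fm <- unclass(fps); sf <- object$sat_fps
  inter <- fm %*% t(sf)
  uni <- outer(rowSums(fm), rowSums(sf), "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  scores <- sweep(sim, 2L, object$projection$centers) %*%
    object$projection$rotation
  colnames(scores) <- colnames(object$projection$scores)
  rownames(scores) <- newdata$id
  scores
}

#' Plot a fitted satellite map
#'
#' Scatter plot of the first two PC scores (PC1 against compound rank when
#' only one PC exists), with satellites highlighted.
#'
#' @param x a fitted `satmap`.
#' @param highlight_satellites draw satellites in a second color.
#' @param ... passed to [graphics::plot()].
#' @export
plot.satmap <- function(x, highlight_satellites = TRUE, ...) {
  s <- x$projection$scores
  is_sat <- seq_len(x$n) %in% x$satellites$indices
  col <- if (highlight_satellites)
    ifelse(is_sat, "#D55E00", "#56B4E9") else "#56B4E9"
  if (ncol(s) >= 2L) {
    graphics::plot(s[, 1], s[, 2], xlab = "PC1", ylab = "PC2",
                   col = col, pch = 16, cex = 0.7,
                   main = "Satellite chemical space map", ...)
  } else {
    graphics::plot(seq_len(nrow(s)), s[, 1], xlab = "compound", ylab = "PC1",
                   col = col, pch = 16, cex = 0.7,
                   main = "Satellite chemical space map (1 PC)", ...)
  }
  if (highlight_satellites)
    graphics::legend("topright", legend = c("satellite", "other"),
                     col = c("#D55E00", "#56B4E9"), pch = 16, bty = "n")
  invisible(x)
}
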