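# Benchmark driver: forward satellite map vs full-matrix gold standard on
# the same library, with wall-clock timings (reported, never asserted — they
# are hardware-dependent).

#' Benchmark the satellite map against the gold standard
#'
#' Runs the forward procedure and the full-matrix gold standard on the same
#' library, reports the validation correlation between the two maps'
#' pairwise distances, the satellite fraction the forward run used, the
#' stage-to-stage correlations, and elapsed wall-clock seconds for each
#' route.  Fingerprinting is shared and timed separately.
#'
#' @param library a `chem_library` with at least 3 molecules.
#' @param config a [map_config()].
#' @return A `map_benchmark` list: `n`, `fraction_used`, `validation_r`,
#'   `stage_correlations`, `converged`, `fit` (the `satmap`), and `timings`
#'   (seconds: `fingerprints`, `gold_standard`, `satellites`).
#' @export
benchmark_map <- function(library, config = map_config()) {
  t_fp <- system.time(
    fps <- library_fingerprints(library, config$fp_type, config$n_bits)
  )[["elapsed"]]
  t_gold <- system.time(
    gs <- gold_standard(fps, n_pcs = config$n_pcs)
  )[["elapsed"]]
  t_sat <- system.time(
    fit <- satmap(library, config, fps = fps)
  )[["elapsed"]]
  validation_r <- distance_correlation(
    gs$distances, pairwise_distances(fit$projection))
  fit$validation_r <- validation_r
  structure(list(
    n = length(library),
    fraction_used = length(fit$satellites) / length(library),
    validation_r = validation_r,
    stage_correlations = fit$stages$r[-1],
    converged = fit$converged,
    fit = fit,
    timings = list(fingerprints = t_fp, gold_standard = t_gold,
                   satellites = t_sat)),
    class = "map_benchmark")
}

#' @export
print.map_benchmark <- function(x, ...) {
  cat(sprintf("Satellite map benchmark: N = %d\n", x$n))
  cat(sprintf("  satellite fraction used: %.2f (%d compounds)\n",
              x$fraction_used, length(x$fit$satellites)))
  cat(sprintf("  validation correlation vs gold standard: %.4f\n",
              x$validation_r))
  if (length(x$stage_correlations))
    cat("  stage-to-stage correlations:",
        paste(sprintf("%.3f", x$stage_correlations), collapse = ", "), "\n")
  cat(sprintf("  timings (s): fingerprints %.2f, gold standard %.2f, satellites %.2f\n",
              x$timings$fingerprints, x$timings$gold_standard,
              x$timings$satellites))
  invisible(x)
}
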