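# Satellite selection: random or MaxMin diversity picking, plus incremental
# growth with the prefix property (a grown set always starts with the
# original selection sequence, so previously computed similarity columns
# stay valid).

new_satellite_set <- function(indices, strategy, seed, n_total,
                              saturated = FALSE) {
  structure(list(indices = as.integer(indices), strategy = strategy,
                 seed = as.integer(seed), n_total = as.integer(n_total),
                 saturated = isTRUE(saturated)),
            class = "satellite_set")
}

#' @export
print.satellite_set <- function(x, ...) {
  cat(sprintf("Satellite set: %d of %d compounds, strategy=%s, seed=%d%s\n",
              length(x$indices), x$n_total, x$strategy, x$seed,
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' @export
length.satellite_set <- function(x) length(x$indices)

#' Select satellites uniformly at random
#'
#' Draws `k` unique 1-based indices without replacement.  Selections are
#' prefix-consistent: for a fixed seed, the first `k'` indices of a size-`k`
#' selection equal the size-`k'` selection.
#'
#' @param n_total library size N.
#' @param k number of satellites, `1 <= k <= n_total`.
#' @param seed integer RNG seed; the caller's RNG stream is left untouched.
#' @return A `satellite_set`.
#' @export
select_random <- function(n_total, k, seed = 1L) {
  if (k < 1L || k > n_total) satmap_error("k out of range")
  perm <- with_seed(seed, sample.int(n_total))
  new_satellite_set(perm[seq_len(k)], "random", seed, n_total,
                    saturated = k == n_total)
}

# Continue a MaxMin sequence: `selected` already picked, `min_dist` is each
# compound's minimum Tanimoto distance (1 - similarity) to the selected set
# (-Inf for selected compounds).  Ties go to the lowest index (which.max).
maxmin_extend <- function(fps, selected, min_dist, n_new) {
  for (j in seq_len(n_new)) {
    pick <- which.max(min_dist)
    selected <- c(selected, pick)
    d_new <- 1 - as.vector(tanimoto_cross(fps, pick))
    min_dist <- pmin(min_dist, d_new)
    min_dist[pick] <- -Inf
  }
  selected
}

#' Select satellites by MaxMin diversity
#'
#' The first compound is drawn at random (seeded); each subsequent pick
#' maximizes its minimum Tanimoto distance (1 - similarity) to all compounds
#' already selected, ties broken by the lowest index.  Distances use the same
#' fingerprint type as the map, via the supplied `fp_matrix`.
#'
#' @param fps an `fp_matrix` from [library_fingerprints()].
#' @inheritParams select_random
#' @return A `satellite_set`.
#' @export
select_maxmin <- function(fps, k, seed = 1L) {
  n <- nrow(fps)
  if (k < 1L || k > n) satmap_error("k out of range")
  first <- with_seed(seed, sample.int(n, 1L))
  min_dist <- 1 - as.vector(tanimoto_cross(fps, first))
  min_dist[first] <- -Inf
  idx <- maxmin_extend(fps, first, min_dist, k - 1L)
  new_satellite_set(idx, "maxmin", seed, n, saturated = k == n)
}

#' Grow a satellite set by its own strategy
#'
#' Appends `additional` new satellites from the unselected pool, preserving
#' the existing selection sequence as a prefix.  Random sets draw the new
#' indices uniformly from the pool under `seed`; MaxMin sets continue the
#' deterministic MaxMin sequence.  When the pool is exhausted the set
#' saturates at all N compounds and is flagged.
#'
#' @param set a `satellite_set`.
#' @param fps the library `fp_matrix` (needed for MaxMin growth; random
#'   growth only uses its row count).
#' @param additional number of satellites to append (>= 1).
#' @param seed RNG seed for random growth; defaults to the set's seed + 1.
#' @return A grown `satellite_set`.
#' @export
grow_satellites <- function(set, fps, additional, seed = set$seed + 1L) {
  if (additional < 1L) satmap_error("additional must be >= 1")
  n <- set$n_total
  pool <- setdiff(seq_len(n), set$indices)
  n_new <- min(additional, length(pool))
  if (n_new == 0L)
    return(new_satellite_set(set$indices, set$strategy, set$seed, n,
                             saturated = TRUE))
  if (set$strategy == "random") {
    add <- with_seed(seed, pool[sample.int(length(pool), n_new)])
    idx <- c(set$indices, add)
  } else {
    sims <- tanimoto_cross(fps, set$indices)
    min_dist <- 1 - apply(sims, 1L, max)
    min_dist[set$indices] <- -Inf
    idx <- maxmin_extend(fps, set$indices, min_dist, n_new)
  }
  new_satellite_set(idx, set$strategy, set$seed, n,
                    saturated = length(idx) == n)
}

#' Serialize / restore a satellite set
#'
#' Plain-text format for resuming runs: a header line with strategy, seed and
#' N, then one selected index per line in selection order.
#'
#' @param set a `satellite_set`.
#' @param path output file.
#' @return `path` (write) or a `satellite_set` (read).
#' @export
write_satellites <- function(set, path) {
  header <- sprintf("# strategy=%s seed=%d n_total=%d saturated=%d",
                    set$strategy, set$seed, set$n_total,
                    as.integer(set$saturated))
  writeLines(c(header, as.character(set$indices)), path)
  invisible(path)
}

#' @rdname write_satellites
#' @export
read_satellites <- function(path) {
  lines <- readLines(path)
  h <- lines[1]
  get_field <- function(name)
    as.integer(sub(sprintf(".*%s=([-0-9]+).*", name), "\\1", h))
  strategy <- sub(".*strategy=([a-z]+).*", "\\1", h)
  new_satellite_set(as.integer(lines[-1]), strategy, get_field("seed"),
                    get_field("n_total"), saturated = get_field("saturated") == 1L)
}
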