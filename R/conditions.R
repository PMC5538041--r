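# Internal condition constructors and small shared utilities.

# Degenerate-geometry failures (all compounds identical, zero-variance
# similarity matrix, constant distance vector) get their own condition class
# so callers can distinguish them from programming errors.
degenerate_geometry_error <- function(message, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c("satmap_degenerate_geometry", "satmap_error"),
                      call = call))
}

satmap_error <- function(message, call = sys.call(-1)) {
  stop(errorCondition(message, class = "satmap_error", call = call))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
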