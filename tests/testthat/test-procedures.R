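test_that("backwards sweep traces every satellite count for every repeat", {
  lib <- fix_library(20, "mixed")
  fps <- fix_fps(20, "mixed")
  cv <- backwards_run(lib, map_config(n_repeats = 2, base_seed = 5), fps = fps)
  expect_s3_class(cv, "correlation_curves")
  expect_equal(nrow(cv), 2 * 19)
  for (r in 1:2) {
    cur <- cv[cv[["repeat"]] == r, ]
    expect_equal(cur$k, 1:19)            # k strictly increasing, 1 .. N-1
    expect_equal(cur$fraction, cur$k / 20)
    expect_true(all(is.na(cur$r) | (cur$r >= -1 & cur$r <= 1)))
  }
  # distinct seeds give distinct curves; same config reruns identically
  expect_false(identical(cv$r[cv[["repeat"]] == 1], cv$r[cv[["repeat"]] == 2]))
  cv2 <- backwards_run(lib, map_config(n_repeats = 2, base_seed = 5), fps = fps)
  expect_identical(cv$r, cv2$r)
})

test_that("near-full satellite sets reproduce the gold standard", {
  lib <- fix_library(20, "congeneric")
  fps <- fix_fps(20, "congeneric")
  cv <- backwards_run(lib, map_config(n_repeats = 3, base_seed = 1), fps = fps)
  expect_true(all(cv$r[cv$k == 19] > 0.99))
})

test_that("threshold fraction uses the sustained-crossing rule", {
  curve <- function(r) data.frame(k = seq_along(r), r = r)
  # dips after a first touch do not count; the last upcrossing wins
  expect_equal(satellites_fraction_for_threshold(
    curve(c(0.5, 0.95, 0.85, 0.92, 0.95)), 0.9, n = 6), 4 / 6)
  # always above: smallest k observed
  expect_equal(satellites_fraction_for_threshold(
    curve(c(0.95, 0.97, 0.99)), 0.9, n = 4), 1 / 4)
  # never sustained: 1.0
  expect_equal(satellites_fraction_for_threshold(
    curve(c(0.5, 0.95, 0.85)), 0.9, n = 4), 1.0)
  # missing entries (degenerate small-k) are excluded before scanning
  expect_equal(satellites_fraction_for_threshold(
    curve(c(NA, 0.95, 0.91, 0.93)), 0.9, n = 5), 2 / 5)
})

test_that("forward procedure follows the 25% + 5% schedule and terminates", {
  lib <- fix_library(100, "congeneric")
  fps <- fix_fps(100, "congeneric")
  fit <- satmap(lib, map_config(base_seed = 1), fps = fps)
  expect_s3_class(fit, "satmap")
  expect_equal(fit$stages$k[1], 25L)            # ceil(0.25 * 100)
  expect_true(all(diff(fit$stages$k) == 5L))    # ceil(0.05 * 100) per stage
  expect_lte(nrow(fit$stages), ceiling(0.75 / 0.05) + 1)
  expect_true(fit$converged)
  # stage correlations live in the stage table, NA for the first stage
  expect_true(is.na(fit$stages$r[1]))
  expect_true(all(!is.na(fit$stages$r[-1])))
  # an unreachable threshold saturates at the full library and converges
  sat_fit <- satmap(lib, map_config(corr_threshold = 1, base_seed = 1),
                    fps = fps)
  expect_true(sat_fit$saturated)
  expect_equal(length(sat_fit$satellites), 100L)
  expect_equal(nrow(sat_fit$stages), ceiling(0.75 / 0.05) + 1)
})

test_that("forward stages reuse satellite columns bit-identically", {
  fps <- fix_fps(60, "congeneric")
  base <- select_random(60, 15, seed = 4)
  grown <- grow_satellites(base, fps, 3, seed = 8)
  s_before <- similarity_matrix(fps, base)
  s_after <- similarity_matrix(fps, grown)
  expect_identical(unclass(s_after)[, 1:15], unclass(s_before)[, 1:15])
})

test_that("forward run converges within two stages on a congeneric library", {
  lib <- fix_library(100, "congeneric")
  fps <- fix_fps(100, "congeneric")
  stages <- sapply(1:5, function(s)
    nrow(satmap(lib, map_config(base_seed = s), fps = fps)$stages))
  expect_gte(sum(stages <= 2), 4)
})

test_that("predict projects satellites back onto their fitted positions", {
  lib <- fix_library(60, "congeneric")
  fps <- fix_fps(60, "congeneric")
  fit <- satmap(lib, map_config(base_seed = 2), fps = fps)
  # refitting the fitted library reproduces the stored scores
  scores <- predict(fit, lib)
  expect_equal(unname(scores), unname(fit$projection$scores),
               tolerance = 1e-9)
  expect_identical(predict(fit), fit$projection$scores)
  # single new compound gets finite in-plane coordinates
  one <- predict(fit, "O=C(Nc1ccc(F)cc1)c1ccccc1")
  expect_equal(dim(one), c(1L, fit$projection$n_pcs_effective))
  expect_true(all(is.finite(one)))
})

test_that("benchmark couples forward fit and gold standard coherently", {
  lib <- fix_library(60, "congeneric")
  bm <- benchmark_map(lib, map_config(base_seed = 3))
  expect_s3_class(bm, "map_benchmark")
  expect_lte(bm$fraction_used, 1.0)
  expect_gte(bm$validation_r, -1)
  expect_lte(bm$validation_r, 1)
  # validation correlation is coupled to the final stage-to-stage value
  final_stage_r <- utils::tail(bm$stage_correlations, 1)
  expect_gte(bm$validation_r, final_stage_r - 0.1)
  # timings are reported as numbers, never asserted against references
  expect_true(all(vapply(bm$timings, is.numeric, logical(1))))
})

test_that("random selection gives smoother curves on the diverse fixture", {
  lib <- fix_library(60, "mixed")
  fps <- fix_fps(60, "mixed")
  roughness <- function(strategy) {
    cv <- backwards_run(lib, map_config(strategy = strategy, n_repeats = 5,
                                        base_seed = 1), fps = fps)
    mean(sapply(1:5, function(rep) {
      r <- cv$r[cv[["repeat"]] == rep]
      mean(diff(r[!is.na(r)])^2)
    }))
  }
  expect_lt(roughness("random"), roughness("maxmin"))
})
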