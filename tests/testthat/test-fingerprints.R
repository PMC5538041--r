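make_fp <- function(bits, len = 8L, type = "ecfp4") {
  structure(as.integer(bits), length = as.integer(len), fp_type = type,
            class = "fingerprint")
}

test_that("fingerprints are canonical-SMILES invariant and type-correct", {
  for (tp in c("ecfp4", "maccs")) {
    a <- fingerprint("CCO", tp)
    b <- fingerprint("OCC", tp)
    expect_identical(unclass(a), unclass(b))
    expect_equal(attr(a, "fp_type"), tp)
  }
  expect_equal(attr(fingerprint("CCO", "maccs"), "length"), 166L)
  expect_equal(attr(fingerprint("CCO", "ecfp4", n_bits = 1024), "length"), 1024L)
  # methane fires very few MACCS structural keys
  expect_lt(length(unclass(fingerprint("C", "maccs"))), 10L)
  # benzene and pyridine differ in ECFP4
  benz <- fingerprint("c1ccccc1", "ecfp4")
  pyr <- fingerprint("c1ccncc1", "ecfp4")
  expect_false(identical(unclass(benz), unclass(pyr)))
})

test_that("tanimoto matches hand counts and enforces its conventions", {
  expect_equal(tanimoto(make_fp(c(1, 2, 3)), make_fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(make_fp(c(1, 5)), make_fp(c(1, 5))), 1.0)
  expect_equal(tanimoto(make_fp(c(1, 2)), make_fp(c(3, 4))), 0.0)
  # both-empty convention
  expect_equal(tanimoto(make_fp(integer(0)), make_fp(integer(0))), 0.0)
  # mismatched type or length is an error
  expect_error(tanimoto(make_fp(1, len = 8), make_fp(1, len = 16)),
               class = "satmap_error")
  expect_error(tanimoto(make_fp(1, type = "maccs"), make_fp(1)),
               class = "satmap_error")
})

test_that("tanimoto is symmetric and 1 on the diagonal (property)", {
  fps <- fix_fps(20, "mixed")
  set.seed(42)
  for (case in 1:20) {
    ij <- sample(nrow(fps), 2)
    a <- as_fingerprint(fps, ij[1]); b <- as_fingerprint(fps, ij[2])
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(a, a), 1.0)
  }
})

test_that("the similarity matrix agrees with scalar tanimoto and fpSim", {
  fps <- fix_fps(20, "mixed")
  sats <- c(3L, 7L, 11L)
  sim <- similarity_matrix(fps, sats)
  expect_equal(dim(sim), c(20L, 3L))
  expect_true(all(sim >= 0 & sim <= 1))
  # spot-check against the scalar path
  for (i in c(1L, 5L, 19L)) for (j in seq_along(sats))
    expect_equal(sim[i, j],
                 tanimoto(as_fingerprint(fps, i), as_fingerprint(fps, sats[j])))
  # cross-check a full column against ChemmineR's fpSim (independent oracle)
  fpset <- methods::new("FPset", fpma = unclass(fps), type = "ecfp4",
                        foldCount = 0L)
  ref <- ChemmineR::fpSim(fpset[3], fpset, sorted = FALSE, addone = 0)
  expect_equal(unname(sim[, 1]), unname(ref), tolerance = 1e-12)
})

test_that("self-similarity and full-satellite symmetry hold", {
  fps <- fix_fps(20, "congeneric")
  n <- nrow(fps)
  # k = 1: an N x 1 matrix whose satellite row is exactly 1
  one <- similarity_matrix(fps, 5L)
  expect_equal(dim(one), c(n, 1L))
  expect_equal(one[5, 1], 1.0)
  # satellites = full library: symmetric with unit diagonal
  full <- similarity_matrix(fps, seq_len(n))
  expect_equal(unclass(full), t(unclass(full)), ignore_attr = TRUE)
  expect_equal(unname(diag(full)), rep(1, n))
  # bad satellite lists error
  expect_error(similarity_matrix(fps, integer(0)), class = "satmap_error")
  expect_error(similarity_matrix(fps, c(1L, 1L)), class = "satmap_error")
  expect_error(similarity_matrix(fps, n + 1L), class = "satmap_error")
})

test_that("median pairwise similarity behaves as an internal diversity metric", {
  lib2 <- fix_toy()[1:2]
  fps2 <- library_fingerprints(lib2, "ecfp4")
  expect_equal(median_pairwise_similarity(fps2),
               tanimoto(as_fingerprint(fps2, 1), as_fingerprint(fps2, 2)))
  # identical molecules: median 1
  same <- as_chem_library(c("CCO", "OCC"))
  expect_equal(median_pairwise_similarity(same, "maccs"), 1.0)
  expect_error(median_pairwise_similarity(fix_toy()[1]), class = "satmap_error")
  # permutation invariance of input order
  fps <- fix_fps(20, "mixed", "maccs")
  set.seed(9)
  perm <- structure(unclass(fps)[sample(nrow(fps)), ],
                    fp_type = "maccs", class = "fp_matrix")
  expect_equal(median_pairwise_similarity(perm),
               median_pairwise_similarity(fps))
})

test_that("fixture libraries fall in the intended diversity regimes", {
  lib_c <- fix_library(50, "congeneric")
  lib_m <- fix_library(50, "mixed")
  med_c <- median_pairwise_similarity(lib_c, "maccs")
  med_m <- median_pairwise_similarity(lib_m, "maccs")
  # congeneric series: low-diversity regime; mixed scaffolds: diverse regime
  expect_gte(med_c, 0.6)
  expect_lte(med_m, 0.5)
  expect_gt(med_c, med_m)
})
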