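---
title: "Satellite similarity maps: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellite similarity maps: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmap)
```

## The model

A chemical space map here is a low-dimensional embedding of a compound
library obtained by PCA of a fingerprint-similarity matrix. Given N
molecules and a subset of k *satellites*, the data matrix is
S ∈ [0,1]^(N×k), with S[i,j] the Tanimoto similarity between compound i and
satellite j. Every compound — satellites included — gets a row, so a
compound's entry against itself is exactly 1. The map is the projection of
the column-centered S onto its top 2 or 3 right singular directions.

The quantity the method cares about is not the coordinates themselves
(PCA axes are arbitrary up to rotation and sign) but the **geometry**: the
condensed vector of all N(N−1)/2 pairwise Euclidean distances in score
space. Two maps are compared by the Pearson correlation of their distance
vectors, which is invariant to any orthogonal transform of either map. The
reference (*gold standard*) is the 2- or 3-PC map of the full N×N matrix —
deliberately **not** the full-dimensional distances, because the object of
interest is the best 2D/3D visualization, and that is what a reduced map
could at best reproduce.

The working assumption is that a library's similarity structure is
effectively low-rank: a modest, representative satellite subset spans
nearly the same dominant directions as the full matrix. That holds well for
focused libraries (congeneric series, low internal diversity) and
progressively worse for diverse collections, which is exactly what the
backwards experiment measures.

## Procedures

**Forward (production), `satmap()`.** Start with ⌈`start_fraction`·N⌉
satellites, append ⌈`step_fraction`·N⌉ per stage by the same selection
strategy (growth preserves the earlier picks as a prefix, so similarity
columns are computed once), and stop when the distance vectors of
consecutive stages correlate at `corr_threshold` or better, or the set
saturates at N. The stage bound ⌈(1−start)/step⌉+1 makes termination
unconditional. The stopping rule compares *consecutive stages*, never the
gold standard — computing the full matrix would defeat the method; the
gold-standard comparison (`validation_r`) exists only in
`benchmark_map()`/`validate = TRUE` for study purposes.

**Backwards (validation), `backwards_run()`.** With the full matrix in
hand, sweep k = 1…N−1 and correlate each reduced map against the gold
standard, five times with seeds `base_seed + 0…4`. The summary statistic,
`satellites_fraction_for_threshold()`, uses a **sustained**-crossing rule:
the smallest k/N such that the curve never dips below the threshold again.
A single-touch rule would overstate stability, since the curves fluctuate.

## Parameters

| parameter | default | rationale |
|---|---|---|
| `fp_type` | `ecfp4` | circular fingerprint of diameter 4 (radius-2 neighborhoods); the standard choice for similarity maps. MACCS (166 keys) offered for diversity profiling |
| `n_bits` | 2048 | common hashed length; the toolkit computes 4096 bits which are OR-folded in halves — any power-of-two divisor ≥ 64 works |
| `n_pcs` | 2 | 2-PC maps were slightly better and more stable than 3-PC in validation sweeps; 3 supported |
| `strategy` | `random` | uniform sampling without replacement; `maxmin` (each pick maximizes its minimum Tanimoto distance to those already picked) offered for comparison |
| `start_fraction` | 0.25 | backwards sweeps show low-diversity libraries sustain r ≥ 0.9 near 25% satellites |
| `step_fraction` | 0.05 | small enough to stop promptly after convergence, large enough to progress |
| `corr_threshold` | 0.9 | the conventional bar for a "high" correlation in this protocol |
| `n_repeats` | 5 | enough to see run-to-run stability without dominating runtime |

Fraction-to-count conversion is ⌈fraction·N⌉, capped at N.

## Numerical choices

- **Centering, no scaling.** Columns are mean-centered only: all features
  are Tanimoto similarities on one [0,1] scale, so variance scaling would
  only amplify noise in near-constant columns.
- **SVD-based PCA** for numerical stability; the test suite checks
  equivalence against an independent covariance-eigendecomposition oracle
  at 1e-9. Each PC's sign is fixed (largest-magnitude loading positive) so
  runs are bit-reproducible; signs cannot affect distances.
- **Effective dimension.** `n_pcs_effective = min(n_pcs, k, rank)`: one
  satellite admits one PC. Rank uses the standard spectral tolerance
  `max(dim) · eps · d₁`.
- **Degenerate geometry.** An all-identical library (zero-variance matrix,
  or a constant distance vector) raises a dedicated condition class rather
  than propagating NaN. The backwards sweep records such k as `NA` and
  continues; the forward fit treats it as fatal with a diagnostic. `NA`
  entries are excluded from threshold estimation.
- **Tanimoto conventions.** Two empty fingerprints have similarity 0 (a
  documented convention; no similarity evidence exists). MaxMin ties break
  to the lowest compound index, making selection fully deterministic given
  the seed of the first pick.
- **Condensed order.** Distance vectors use the (1,2), (1,3), …, (2,3), …
  upper-triangle order throughout.
- **Seeding.** Every stochastic step takes an explicit seed and restores
  the caller's RNG state; repeats use `base_seed + repeat − 1`.

## Chemistry layer

Structures are parsed and canonicalized by OpenBabel (via
ChemmineR/ChemmineOB). Standardization keeps the largest covalent fragment
— most heavy atoms, ties by total atoms then lexicographically smallest
canonical SMILES — and neither neutralizes charges nor canonicalizes
tautomers: the minimal, reproducible rule set. Records failing sanitization
are skipped and counted, never fatal unless nothing remains. MACCS
fingerprints arrive padded to 256 bits and are truncated to the 166 defined
keys after checking the padding is empty. One naming caveat: some toolkits
label the diameter-4 circular fingerprint "radius 4"; this package follows
the community meaning (ECFP4 = radius 2) throughout. Fingerprint bit
patterns differ between toolkits (aromaticity perception, hashing), so
diversity medians computed here can differ from other software by a few
hundredths.

## The synthetic libraries

`generate_library()` provides the two diversity regimes the procedures are
studied on, with no external downloads:

- **Congeneric** (low diversity): one benzanilide scaffold, two decoration
  points drawn from six conservative substituents with Zipf-like weights
  (common groups reused heavily, as in real series), and one all-carbon
  anchor point (parent / cyclopropyl / n-butyl) that splits the series into
  three sub-series. The anchors shift circular-fingerprint environments —
  giving the series the clustered, low-rank similarity structure real
  focused libraries show — while leaving MACCS fragment keys largely
  untouched, so the median MACCS similarity stays in the focused-library
  regime (≈ 0.6–0.67 across seeds and sizes). A uniform decoration scheme
  without the anchor structure produces an unrealistically isotropic
  similarity cloud whose maps need far more satellites than any real
  focused set; the anchor design is what makes the fixture behave like the
  libraries the method targets.
- **Mixed** (high diversity): molecules spread evenly across up to eight
  unrelated drug-like cores, decorated uniformly from a wider pool
  (median MACCS ≈ 0.25).

What the fixtures do **not** emulate: real size distributions (hundreds to
thousands of compounds), tautomers/salts/charge states, stereochemistry,
and the gradual diversity continuum between the two regimes. Passing tests
therefore demonstrate the procedures' behavior in clearly separated
regimes, not performance guarantees on arbitrary real libraries. Diversity
calibration is asserted in the test suite, not assumed.

## Problem sizes

The test suite and the acceptance script run libraries of N = 20–100 and
10×6 random matrices for the oracle checks: large enough for every
procedure to show its behavior (16-stage forward bound, 5-repeat backwards
sweeps in both regimes), small enough that the whole suite completes in
well under a minute of compute on one core.

## Known limitations

- Satellite maps inherit PCA's blind spots: strongly non-linear similarity
  structure is compressed onto 2–3 linear directions, and so is judged only
  through the distance-correlation lens.
- For highly diverse libraries the required satellite fraction approaches
  1, erasing the computational advantage; the diversity median is a useful
  prior check (`median_pairwise_similarity()`).
- On the low-diversity fixture, random and MaxMin selection are equally
  stable — both converge almost immediately — so the advantage of random
  selection (smoother backwards curves) is only observable on the diverse
  fixture, where MaxMin's early picks of outliers distort small-k maps.
  MaxMin's across-seed variance is trivially low (only its first pick is
  random), which is why stability is measured as within-curve roughness,
  not across-repeat variance.
- 3D similarity (conformer-based) maps are out of scope; the maps are as
  2D as their fingerprints.
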