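# Synthetic compound-library generators with controllable internal
# diversity.  A congeneric series (one scaffold, varied substituents)
# emulates a focused, low-2D-diversity inhibitor set; a mixed library drawn
# across unrelated scaffolds emulates a diverse screening collection.  These
# are synthetic stand-ins used by the tests and examples, not real
# bioactivity data.

# Substituent pools: small drug-like decorations written as SMILES branches;
# "" means unsubstituted (H).  The congeneric pool is restricted to
# conservative substituents (halogen, alkyl, ether, amine) so the series
# stays in the low-diversity regime of a focused inhibitor set; strongly
# key-flipping groups (nitro, nitrile, trifluoromethyl) are reserved for the
# mixed pool, where diversity is the point.
default_substituents <- function(mode = c("mixed", "congeneric")) {
  mode <- match.arg(mode)
  if (mode == "congeneric")
    c("", "(F)", "(Cl)", "(C)", "(CC)", "(OC)")
  else
    c("", "(F)", "(Cl)", "(Br)", "(C)", "(CC)", "(OC)", "(O)", "(N)",
      "(C#N)", "(C(F)(F)F)", "([N+](=O)[O-])")
}

# Anchor substituents for the congeneric series: three all-carbon groups at
# the para position of the aniline ring split the series into sub-series
# (parent, cyclopropyl, n-butyl), the way a real med-chem campaign explores
# an attachment point.  All-carbon groups shift circular-fingerprint
# environments (giving the series its cluster structure in map space) while
# leaving most MACCS fragment keys untouched, so the series stays in the
# low-2D-diversity regime.
congeneric_anchors <- function() c("", "(C2CC2)", "(CCCC)")

# Scaffold templates: {R1}, {R2}, ... mark substitution points, each placed
# directly after a ring atom so an empty substituent is syntactically valid.
# The first template (a benzanilide with three substitution points) is the
# congeneric-series core.
scaffold_templates <- function() {
  c(benzanilide   = "O=C(Nc1ccc{R1}c{R2}c1)c1ccc{R3}cc1",
    quinoline     = "Nc1cc{R1}nc2ccc{R2}cc12",
    piperazine    = "C{R1}N1CCN(CC1)c1ccc{R2}cc1",
    sulfonamide   = "O=S(=O)(NC{R1})c1ccc{R2}cc1",
    cyclohexamide = "O=C(NC{R1})C1CCC{R2}CC1",
    thiophene     = "O=C(N{R1})c1cc{R2}cs1",
    pyridine      = "C{R1}Oc1ccnc{R2}c1",
    naphthalene   = "OC(=O)c1ccc2cc{R1}ccc2c1")
}

fill_template <- function(template, subs) {
  for (i in seq_along(subs))
    template <- sub(sprintf("{R%d}", i), subs[i], template, fixed = TRUE)
  template
}

n_slots <- function(template)
  length(gregexpr("\\{R[0-9]+\\}", template)[[1]])

# Decode combo index (1-based) into substituent choices for `slots` slots
# over a pool of size s.
combo_subs <- function(index, slots, pool) {
  i <- index - 1L
  s <- length(pool)
  subs <- character(slots)
  for (j in seq_len(slots)) {
    subs[j] <- pool[(i %% s) + 1L]
    i <- i %/% s
  }
  subs
}

#' Generate a synthetic compound library
#'
#' Congeneric mode emulates a focused medicinal-chemistry series: one
#' benzanilide scaffold whose aniline ring carries two decoration points
#' drawn from a conservative substituent pool with Zipf-like frequencies
#' (common groups are reused heavily, as in real series) and one anchor
#' position that splits the series into three sub-series (parent,
#' cyclopropyl, n-butyl).  The result sits in the low-2D-diversity regime of
#' a focused inhibitor set (median MACCS similarity around 0.6 or higher)
#' with the clustered, low-rank similarity structure such series show.
#' Mixed mode spreads molecules evenly across `n_scaffolds` unrelated
#' drug-like cores decorated uniformly at random, giving a diverse screening
#' collection (median MACCS below 0.5).  All outputs are valid,
#' standardizable, unique SMILES; generation is deterministic per seed.
#'
#' @param n number of molecules (>= 2; congeneric capacity is 108 with the
#'   default pool).
#' @param mode `"congeneric"` or `"mixed"`.
#' @param n_scaffolds number of distinct cores in mixed mode (2 to 8).
#' @param seed integer seed.
#' @param substituent_pool optional character vector of SMILES branch
#'   fragments (e.g. `"(F)"`) for the decoration points; `""` means
#'   unsubstituted.
#' @return Character vector of `n` unique SMILES.
#' @examples
#' head(generate_library(10, "congeneric", seed = 7))
#' @export
generate_library <- function(n, mode = c("congeneric", "mixed"),
                             n_scaffolds = 8L, seed = 7L,
                             substituent_pool = NULL) {
  mode <- match.arg(mode)
  if (n < 2L) satmap_error("n must be >= 2")
  pool <- substituent_pool %||% default_substituents(mode)
  templates <- scaffold_templates()
  if (mode == "congeneric")
    return(generate_congeneric(n, pool, seed))
  if (n_scaffolds < 2L || n_scaffolds > length(templates))
    satmap_error(sprintf("n_scaffolds must be in [2, %d]", length(templates)))
  templates <- templates[seq_len(n_scaffolds)]
  # allocate molecules across scaffolds as evenly as possible
  counts <- rep(n %/% length(templates), length(templates))
  extra <- n %% length(templates)
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  capacity <- vapply(templates, function(t) length(pool)^n_slots(t), numeric(1))
  if (any(counts > capacity))
    satmap_error("substituent pool too small for the requested library size")
  with_seed(seed, {
    smiles <- character(0)
    for (t in seq_along(templates)) {
      slots <- n_slots(templates[t])
      combos <- sample.int(capacity[t], counts[t])  # unique per scaffold
      smiles <- c(smiles, vapply(combos, function(ci)
        fill_template(templates[t], combo_subs(ci, slots, pool)),
        character(1)))
    }
    smiles
  })
}

generate_congeneric <- function(n, pool, seed) {
  anchors <- congeneric_anchors()
  template <- scaffold_templates()[["benzanilide"]]
  grid <- expand.grid(r1 = seq_along(pool), r2 = seq_along(pool),
                      r3 = seq_along(anchors))
  if (n > nrow(grid))
    satmap_error("substituent pool too small for the requested library size")
  zipf <- 1 / seq_along(pool)  # common substituents dominate
  weights <- zipf[grid$r1] * zipf[grid$r2]
  with_seed(seed, {
    pick <- sample.int(nrow(grid), n, prob = weights)  # unique combos
    vapply(pick, function(i)
      fill_template(template, c(pool[grid$r1[i]], pool[grid$r2[i]],
                                anchors[grid$r3[i]])),
      character(1))
  })
}
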