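# Reading, standardizing and writing compound libraries.
#
# A `chem_library` holds the standardized molecules of one input file:
# canonical SMILES, identifiers, 1-based source positions, and a load report
# counting records that failed parsing or sanitization.

# -- low-level OpenBabel helpers ---------------------------------------------

# Canonical SMILES of a single SMILES string, or NA if OpenBabel cannot
# parse/sanitize it.  OB signals failure by producing empty output.
ob_canonical <- function(smi) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(smi, "\n"))),
    error = function(e) ""
  )
  out <- strsplit(trimws(out), "[ \t\n]+")[[1]]
  if (length(out) == 0L || !nzchar(out[1])) NA_character_ else out[1]
}

# Heavy (non-hydrogen) atom count read off a SMILES string.  Bracket atoms
# count unless their element is H; outside brackets only the organic subset
# symbols appear as atoms.
heavy_atom_count <- function(smi) {
  brackets <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
  n_br <- 0L
  for (b in brackets) {
    core <- sub("^\\[([0-9]*)", "", b)   # drop "[", isotope digits
    is_h <- grepl("^H($|[^a-z])", core)  # [H], [2H], [H+] but not [Hg], [He]
    if (!is_h) n_br <- n_br + 1L
  }
  rest <- gsub("\\[[^]]*\\]", "", smi)
  m <- gregexpr("Cl|Br|[BCNOPSFIbcnops]", rest)[[1]]
  n_org <- if (m[1] == -1L) 0L else length(m)
  n_br + n_org
}

# Total atom count (hydrogens included) via an explicit-H SDF conversion;
# falls back to the heavy-atom count if the conversion fails (single atoms,
# bare ions).
total_atom_count <- function(smi) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smi, "\n"),
      options = data.frame(names = "h", args = "")
    )),
    error = function(e) ""
  )
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) >= 4L) {
    n <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
    if (!is.na(n)) return(n)
  }
  heavy_atom_count(smi)
}

#' Standardize SMILES strings
#'
#' Standardization keeps the largest covalently bonded fragment of each
#' molecule (stripping salts and counter-ions) and records its canonical
#' SMILES.  The largest fragment is the one with the most heavy atoms; ties
#' fall back to the most total atoms (hydrogens included), then to the
#' lexicographically smallest canonical SMILES.  Charges are not neutralized
#' and tautomers are not canonicalized.  Standardization is idempotent at the
#' canonical-SMILES level.
#'
#' @param smiles character vector of SMILES strings.
#' @return Character vector of the same length: standardized canonical SMILES,
#'   or `NA` where parsing or sanitization failed (including molecules left
#'   with no atoms).
#' @examples
#' \dontrun{
#' standardize_smiles(c("CCO.Cl", "c1ccccc1", "not_a_smiles"))
#' }
#' @export
standardize_smiles <- function(smiles) {
  vapply(smiles, function(smi) {
    if (is.na(smi) || !nzchar(trimws(smi))) return(NA_character_)
    can <- ob_canonical(smi)
    if (is.na(can)) return(NA_character_)
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (length(frags) == 0L) return(NA_character_)
    if (length(frags) > 1L) {
      heavy <- vapply(frags, heavy_atom_count, integer(1))
      cand <- which(heavy == max(heavy))
      if (length(cand) > 1L) {
        tot <- vapply(frags[cand], total_atom_count, integer(1))
        cand <- cand[tot == max(tot)]
      }
      frag <- sort(frags[cand])[1]
      can <- ob_canonical(frag)   # re-canonicalize the isolated fragment
      if (is.na(can)) return(NA_character_)
    }
    if (heavy_atom_count(can) == 0L && !grepl("\\[", can)) return(NA_character_)
    can
  }, character(1), USE.NAMES = FALSE)
}

# -- chem_library construction -----------------------------------------------

new_chem_library <- function(id, smiles, source_index, report) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id)))
  structure(list(id = id, smiles = smiles,
                 source_index = as.integer(source_index),
                 sdf = sdf, report = report),
            class = "chem_library")
}

#' Build a compound library from SMILES strings
#'
#' Each input is standardized (see [standardize_smiles()]); inputs that fail
#' are skipped and counted in the load report, never fatal — unless no valid
#' record remains.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers; defaults to `mol_<i>` by input position.
#' @return A `chem_library`: standardized records in input order with fields
#'   `id`, `smiles` (canonical), `source_index` (1-based input position),
#'   `sdf` (an [ChemmineR::SDFset]) and `report` (counts `n_read`, `n_kept`,
#'   `n_skipped` and `skipped_indices`).
#' @export
as_chem_library <- function(smiles, ids = NULL) {
  n_read <- length(smiles)
  if (n_read == 0L) satmap_error("no input molecules")
  if (is.null(ids)) ids <- paste0("mol_", seq_len(n_read))
  ids[is.na(ids) | !nzchar(ids)] <-
    paste0("mol_", seq_len(n_read))[is.na(ids) | !nzchar(ids)]
  std <- standardize_smiles(smiles)
  keep <- !is.na(std)
  if (!any(keep)) satmap_error("no valid molecules after standardization")
  report <- list(n_read = n_read, n_kept = sum(keep),
                 n_skipped = sum(!keep),
                 skipped_indices = which(!keep))
  new_chem_library(make.unique(ids[keep]), std[keep], which(keep), report)
}

#' Read a compound library from an SDF or SMILES file
#'
#' SMILES files hold one molecule per line, optionally followed by a
#' whitespace-separated identifier.  SDF identifiers come from the molecule
#' title line, falling back to `mol_<i>` when the title is empty.  Individual
#' unparseable records are skipped and counted; an unreadable file or a file
#' with zero valid records is a fatal error.
#'
#' @param path file path.
#' @param format `"sdf"` or `"smiles"`.
#' @return A `chem_library` (see [as_chem_library()]).
#' @export
read_library <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path) || file.size(path) == 0)
    satmap_error(sprintf("file '%s' does not exist or is empty", path))
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) satmap_error("no molecules in file")
    tokens <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(tokens, `[`, character(1), 1L)
    ids <- vapply(tokens, function(x) if (length(x) > 1L) x[2] else NA_character_,
                  character(1))
    return(as_chem_library(smi, ids))
  }
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e)
                       satmap_error(sprintf("cannot read SDF file '%s': %s",
                                            path, conditionMessage(e))))
  n_read <- length(sdfset)
  if (n_read == 0L) satmap_error("no molecules in file")
  smi <- character(n_read)
  for (i in seq_len(n_read)) {
    smi[i] <- tryCatch({
      ok <- ChemmineR::validSDF(sdfset[i])
      if (!ok) NA_character_
      else as.character(suppressWarnings(ChemmineR::sdf2smiles(sdfset[i])))
    }, error = function(e) NA_character_)
  }
  ids <- tryCatch(ChemmineR::sdfid(sdfset), error = function(e) rep("", n_read))
  ids[is.na(ids)] <- ""
  as_chem_library(smi, ifelse(nzchar(trimws(ids)), trimws(ids), NA))
}

#' @export
length.chem_library <- function(x) length(x$smiles)

#' @export
`[.chem_library` <- function(x, i) {
  idx <- seq_along(x$smiles)[i]
  structure(list(id = x$id[idx], smiles = x$smiles[idx],
                 source_index = x$source_index[idx],
                 sdf = x$sdf[idx],
                 report = list(n_read = length(idx), n_kept = length(idx),
                               n_skipped = 0L, skipped_indices = integer(0))),
            class = "chem_library")
}

#' @export
print.chem_library <- function(x, ...) {
  cat(sprintf("Compound library: %d molecules (%d read, %d skipped)\n",
              length(x), x$report$n_read, x$report$n_skipped))
  n_show <- min(5L, length(x))
  for (i in seq_len(n_show))
    cat(sprintf("  %-12s %s\n", x$id[i], x$smiles[i]))
  if (length(x) > n_show) cat(sprintf("  ... and %d more\n", length(x) - n_show))
  invisible(x)
}

# -- coordinate output --------------------------------------------------------

#' Write map coordinates to CSV
#'
#' Writes one row per compound, in library order, with columns `id`, `smiles`
#' and `PC1..PCp`.
#'
#' @param projection a `projection_result` (from [pca_project()]) or a fitted
#'   [satmap()] model.
#' @param library the `chem_library` the projection was computed from.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(projection, library, path) {
  if (inherits(projection, "satmap")) projection <- projection$projection
  scores <- projection$scores
  if (nrow(scores) != length(library))
    satmap_error(sprintf("projection has %d rows but library has %d molecules",
                         nrow(scores), length(library)))
  if (ncol(scores) < 1L) satmap_error("projection has no components")
  df <- data.frame(id = library$id, smiles = library$smiles,
                   scores, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", "smiles", paste0("PC", seq_len(ncol(scores))))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
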