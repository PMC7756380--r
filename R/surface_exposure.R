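# Surface exposure of epitopes from per-residue relative solvent
# accessibility, computed in-repo with a Shrake-Rupley SASA engine.

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# van der Waals radii by element (Bondi set; heavy atoms only)
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                   SE = 1.90)
DEFAULT_RADIUS <- 1.80

# expected heavy-atom counts per residue type (backbone N,CA,C,O + side
# chain); used only to flag residues with missing atoms
AA_HEAVY_ATOMS <- c(
  A = 5, R = 11, N = 8, D = 8, C = 6, Q = 9, E = 9, G = 4, H = 10,
  I = 8, L = 8, K = 9, M = 8, F = 11, P = 7, S = 6, T = 7, W = 14,
  Y = 12, V = 7
)

#' Reference maximum accessible surface areas per residue type
#'
#' Published theoretical (default) and empirical maximum ASA values in
#' square Angstrom for residue X in an extended Gly-X-Gly tripeptide
#' (Tien et al. 2013, PLoS ONE 8:e80635). The computed residue ASA is
#' divided by this reference to obtain the relative accessibility
#' ratio.
#'
#' @param set `"theoretical"` (default) or `"empirical"`.
#' @return Named numeric vector over the 20 one-letter codes.
#' @export
max_asa_table <- function(set = c("theoretical", "empirical")) {
  set <- match.arg(set)
  if (set == "theoretical") {
    c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
      G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
      P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
  } else {
    c(A = 121, R = 265, N = 187, D = 187, C = 148, Q = 214, E = 214,
      G = 97, H = 216, I = 195, L = 191, K = 230, M = 203, F = 228,
      P = 154, S = 143, T = 163, W = 264, Y = 255, V = 165)
  }
}

# Normalize a structure input (path / bio3d pdb / toy_structure) into a
# heavy-atom data.frame: chain, resno, resid, elety, element, x, y, z.
structure_atoms <- function(structure) {
  if (is.character(structure) && length(structure) == 1L) {
    if (!file.exists(structure)) stop("structure file not found: ", structure)
    structure <- bio3d::read.pdb(structure, verbose = FALSE)
  }
  if (inherits(structure, "toy_structure")) {
    at <- structure$atoms
  } else if (inherits(structure, "pdb")) {
    at <- structure$atom  # bio3d keeps only the first model by default
    at <- data.frame(
      record = at$type, chain = at$chain, resno = at$resno, resid = at$resid,
      elety = at$elety, element = at$elesy, x = at$x, y = at$y, z = at$z,
      stringsAsFactors = FALSE
    )
  } else {
    stop("structure must be a file path, a bio3d 'pdb' object or a toy_structure")
  }
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  if (is.null(at$element) || all(is.na(at$element)) || all(at$element == "")) {
    at$element <- substr(trimws(at$elety), 1, 1)
  }
  at$element <- toupper(trimws(at$element))
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0L) stop("structure contains no heavy atoms")
  at
}

#' Per-residue solvent accessibility of a protein structure
#'
#' Computes Shrake-Rupley solvent-accessible surface area per atom
#' (first model, heavy atoms, waters excluded; all non-protein heavy
#' atoms still act as occluders), sums it per residue, and divides by a
#' published per-residue reference maximum to obtain a relative
#' accessibility ratio. A residue is `exposed` when its ratio is
#' strictly greater than 0.5.
#'
#' @param structure PDB file path, `bio3d` pdb object, or
#'   [make_toy_structure()] output.
#' @param probe_radius Water-probe radius in Angstrom (default 1.4).
#' @param n_points Sphere test points per atom (default 960).
#' @param reference Named numeric vector of per-residue maximum ASA;
#'   default [max_asa_table()] ("theoretical").
#' @param sidechain_only If `TRUE`, the ratio uses side-chain atoms only
#'   (CA counts as the glycine side chain) against the same reference;
#'   results are then convention-dependent and flagged in the output.
#' @return Data frame of class `residue_exposure` with columns `chain`,
#'   `resno` (author numbering), `residue_index` (1-based along the
#'   chain), `aa`, `asa`, `ratio`, `exposed`, `incomplete` (missing
#'   heavy atoms; computed from present atoms with a warning).
#' @export
compute_residue_accessibility <- function(structure, probe_radius = 1.4,
                                          n_points = 960,
                                          reference = max_asa_table(),
                                          sidechain_only = FALSE) {
  at <- structure_atoms(structure)
  radii <- unname(ELEMENT_RADII[at$element])
  radii[is.na(radii)] <- DEFAULT_RADIUS
  asa <- sasa_atoms(as.matrix(at[, c("x", "y", "z")]), radii,
                    probe = probe_radius, n_points = as.integer(n_points))
  at$asa <- asa

  prot <- at[at$resid %in% names(AA3_TO_1), , drop = FALSE]
  if (nrow(prot) == 0L) stop("no standard protein residues in structure")
  key <- paste(prot$chain, prot$resno, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(
    chain = prot$chain[first], resno = prot$resno[first],
    aa = unname(AA3_TO_1[prot$resid[first]]), stringsAsFactors = FALSE
  )
  res$residue_index <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)

  backbone <- c("N", "CA", "C", "O", "OXT")
  use <- rep(TRUE, nrow(prot))
  if (sidechain_only) {
    use <- !(trimws(prot$elety) %in% backbone) |
      (prot$resid == "GLY" & trimws(prot$elety) == "CA")
  }
  asa_sum <- tapply(prot$asa * use, key, sum)
  n_atoms <- tapply(rep(1L, nrow(prot)), key, sum)
  res$asa <- as.numeric(asa_sum[paste(res$chain, res$resno, sep = "\r")])
  res$n_atoms <- as.integer(n_atoms[paste(res$chain, res$resno, sep = "\r")])
  res$incomplete <- res$n_atoms < AA_HEAVY_ATOMS[res$aa]
  if (any(res$incomplete)) {
    warning(sum(res$incomplete), " residue(s) with missing heavy atoms; ",
            "accessibility computed from present atoms")
  }
  res$ratio <- res$asa / unname(reference[res$aa])
  res$exposed <- exposure_rule(res$ratio)
  res$n_atoms <- NULL
  res <- res[, c("chain", "resno", "residue_index", "aa", "asa", "ratio",
                 "exposed", "incomplete")]
  rownames(res) <- NULL
  class(res) <- c("residue_exposure", "data.frame")
  res
}

#' Map structure residue indices onto mature-sequence coordinates
#'
#' Author numbering in deposited structures is not trusted; instead the
#' chain sequence is aligned to the mature sequence (global pairwise
#' alignment, BLOSUM62) and `residue_index` is reassigned to the
#' matched mature position. Unaligned residues are dropped with a
#' message.
#'
#' @param exposures `residue_exposure` table for one chain.
#' @param seq [mature_sequence()] defining the coordinate system.
#' @param chain Chain to map (default: first chain in the table).
#' @return `residue_exposure` table with `residue_index` in mature
#'   coordinates.
#' @export
align_exposure_to_mature <- function(exposures, seq, chain = NULL) {
  stopifnot(inherits(seq, "mature_sequence"))
  if (is.null(chain)) chain <- exposures$chain[1]
  ex <- exposures[exposures$chain == chain, , drop = FALSE]
  chain_seq <- paste(ex$aa, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chain_seq), Biostrings::AAString(seq$residues),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  p_chain <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  p_mat <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ci <- cumsum(p_chain != "-")
  mi <- cumsum(p_mat != "-")
  matched <- p_chain != "-" & p_mat != "-"
  map <- rep(NA_integer_, nrow(ex))
  map[ci[matched]] <- mi[matched]
  dropped <- sum(is.na(map))
  if (dropped > 0L) {
    message(dropped, " structure residue(s) not aligned to the mature sequence; dropped")
  }
  ex$residue_index <- map
  ex <- ex[!is.na(ex$residue_index), , drop = FALSE]
  rownames(ex) <- NULL
  class(ex) <- c("residue_exposure", "data.frame")
  ex
}

#' Residue exposure decision rule
#'
#' A residue counts as solvent-exposed when its relative accessibility
#' is strictly greater than the threshold ("greater than 50%"): a
#' ratio of exactly 0.5 is buried.
#'
#' @param ratio Relative accessibility.
#' @param threshold Decision threshold (default 0.5).
#' @return Logical vector.
#' @export
exposure_rule <- function(ratio, threshold = 0.5) {
  !is.na(ratio) & ratio > threshold
}

#' Classify an epitope region as surface-exposed
#'
#' An epitope is surface-exposed when at least `min_fraction` (default
#' 25%) of its residues are individually exposed (relative
#' accessibility strictly greater than 50%). Region residues absent
#' from the exposure table (e.g. unresolved loops) count as not exposed
#' and trigger a warning; a verdict is still returned.
#'
#' @param region Integer vector `c(start, end)` in the coordinate
#'   system of `exposures$residue_index`.
#' @param exposures `residue_exposure` table.
#' @param min_fraction Minimum exposed fraction (default 0.25,
#'   boundary inclusive).
#' @return List with `region_start`, `region_end`, `n_residues`,
#'   `n_exposed`, `n_missing`, `surface_exposed`.
#' @export
classify_epitope_exposure <- function(region, exposures, min_fraction = 0.25) {
  stopifnot(length(region) == 2L, region[1] <= region[2])
  idx <- seq.int(region[1], region[2])
  hit <- match(idx, exposures$residue_index)
  n_missing <- sum(is.na(hit))
  if (n_missing > 0L) {
    warning(n_missing, " region residue(s) absent from the structure; ",
            "counted as not exposed")
  }
  n_exposed <- sum(exposures$exposed[hit[!is.na(hit)]], na.rm = TRUE)
  n <- length(idx)
  list(
    region_start = as.integer(region[1]), region_end = as.integer(region[2]),
    n_residues = n, n_exposed = as.integer(n_exposed),
    n_missing = as.integer(n_missing),
    surface_exposed = (n_exposed / n) >= min_fraction
  )
}

#' Write a residue-exposure table to TSV
#'
#' @param exposures `residue_exposure` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exposure <- function(exposures, path) {
  write.table(as.data.frame(exposures), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
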