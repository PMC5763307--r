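# Residue and atom chemistry lookup tables shared across the package.

#' @keywords internal
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Modified residues translated back to their parent one-letter code when they
# occur in coordinate records (phospho-Ser/Thr/Tyr, selenomethionine, ...).
#' @keywords internal
AA_1TO3 <- structure(names(AA_3TO1), names = unname(AA_3TO1))

#' @keywords internal
MODRES_3TO1 <- c(
  SEP = "S", TPO = "T", PTR = "Y", MSE = "M", CSO = "C", CME = "C",
  OCS = "C", HYP = "P", MLY = "K", ALY = "K", KCX = "K", M3L = "K",
  PCA = "E", CGU = "E", SEC = "C"
)

#' @keywords internal
WATER_CODES <- c("HOH", "DOD", "WAT")

# van der Waals radii (Angstrom) for the elements occurring in protein heavy
# atoms and common ligands; used by the solvent-accessibility calculation.
#' @keywords internal
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, H = 1.20, D = 1.20
)

# Maximum per-residue accessibility (Angstrom^2) in a Gly-X-Gly tripeptide,
# theoretical values of Tien et al. (2013); reference for relative SASA.
#' @keywords internal
MAX_ACC_GXG <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

#' @keywords internal
ACIDIC_AA <- c("D", "E")
#' @keywords internal
BASIC_AA <- c("K", "R", "H")

# Charged-group atoms admitted to the salt-bridge N-O criterion.  Restricting
# to these keeps the 5.5 A rule from subsuming every backbone hydrogen bond.
#' @keywords internal
SALT_BASIC_ATOMS <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)
#' @keywords internal
SALT_ACIDIC_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

#' @keywords internal
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Common crystallization additives excluded from ligand extraction by default.
#' @keywords internal
LIGAND_BLOCKLIST <- c(
  "SO4", "GOL", "PEG", "EDO", "PO4", "ACT", "DMS", "FMT",
  "MPD", "TRS", "NO3", "IMD", "EPE", "MES", "BME", "PG4"
)

#' Side-chain functional atom per residue type
#'
#' Returns the terminal side-chain atom used to define a neighboring residue's
#' side-chain direction (the vector from its C-alpha to this atom). Glycine has
#' no side chain and maps to `NA`. The table can be overridden entry-wise.
#'
#' @param overrides optional named character vector (one-letter residue code to
#'   atom name) replacing individual entries.
#' @return named character vector over the 20 standard one-letter codes.
#' @export
#' @examples
#' functional_atom_table()[["S"]]  # "OG"
functional_atom_table <- function(overrides = NULL) {
  tab <- c(
    S = "OG", T = "OG1", Y = "OH", K = "NZ", R = "CZ",
    D = "CG", E = "CD", N = "CG", Q = "CD", H = "NE2",
    C = "SG", M = "SD", W = "NE1", F = "CZ", L = "CG",
    I = "CG1", V = "CB", A = "CB", P = "CG", G = NA_character_
  )
  if (!is.null(overrides)) {
    stopifnot(is.character(overrides), !is.null(names(overrides)))
    tab[names(overrides)] <- overrides
  }
  tab
}

#' PTM target atom per (modification type, residue)
#'
#' The target atom is the side-chain atom to which the modifying group attaches
#' (e.g. ND2 of Asn for N-linked glycosylation, OG of Ser for phosphorylation).
#' It anchors the orientation-angle and radial-composition reference point.
#'
#' @param overrides optional named character vector with names of the form
#'   `"<ptm_type>|<residue_code>"` (e.g. `"phosphorylation|S"`).
#' @return data.frame with columns `ptm_type`, `residue`, `atom`.
#' @export
#' @examples
#' tab <- target_atom_table()
#' tab[tab$ptm_type == "n-linked glycosylation", ]
target_atom_table <- function(overrides = NULL) {
  entries <- c(
    "phosphorylation|S" = "OG",
    "phosphorylation|T" = "OG1",
    "phosphorylation|Y" = "OH",
    "dephosphorylation|S" = "OG",
    "dephosphorylation|T" = "OG1",
    "dephosphorylation|Y" = "OH",
    "n-linked glycosylation|N" = "ND2",
    "o-linked glycosylation|S" = "OG",
    "o-linked glycosylation|T" = "OG1",
    "s-linked glycosylation|C" = "SG",
    "c-linked glycosylation|W" = "CD1",
    "acetylation|K" = "NZ",
    "ubiquitylation|K" = "NZ",
    "sumoylation|K" = "NZ",
    "neddylation|K" = "NZ",
    "methylation|K" = "NZ",
    "methylation|R" = "NH1",
    "succinylation|K" = "NZ",
    "malonylation|K" = "NZ",
    "carboxylation|K" = "NZ",
    "glycation|K" = "NZ",
    "s-nitrosylation|C" = "SG",
    "glutathionylation|C" = "SG",
    "palmitoylation|C" = "SG",
    "prenylation|C" = "SG",
    "disulfide bond|C" = "SG"
  )
  if (!is.null(overrides)) {
    stopifnot(is.character(overrides), !is.null(names(overrides)))
    entries[names(overrides)] <- overrides
  }
  parts <- strsplit(names(entries), "|", fixed = TRUE)
  data.frame(
    ptm_type = vapply(parts, `[`, "", 1L),
    residue = vapply(parts, `[`, "", 2L),
    atom = unname(entries),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
aa_one_letter <- function(res_name) {
  res_name <- toupper(res_name)
  out <- AA_3TO1[res_name]
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- MODRES_3TO1[res_name[miss]]
    out[is.na(out)] <- "X"
  }
  unname(out)
}

#' @keywords internal
is_standard_or_modified_aa <- function(res_name) {
  toupper(res_name) %in% c(names(AA_3TO1), names(MODRES_3TO1))
}
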