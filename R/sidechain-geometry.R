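# Side-chain orientation of residues spatially neighboring a PTM site.
#
# For substrate site p with target atom position X_p (the side-chain atom the
# modifying group attaches to) and a neighboring residue k:
#   S_k = X_p - X_k(Calpha)          (neighbor -> substrate vector)
#   V_k = X_k(F) - X_k(Calpha)       (side-chain direction, F = functional atom)
#   theta_k = arccos( S_k . V_k / (|S_k| |V_k|) )
# A neighbor is considered functionally oriented toward the site when
# theta_k < 80 degrees (strict).

#' Angle between two 3-vectors in degrees
#'
#' @param u,v numeric 3-vectors.
#' @return angle in degrees in [0, 180]; the arccos argument is clamped to
#'   [-1, 1] against rounding.
#' @export
vector_angle <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length vector: angle undefined")
  arg <- sum(u * v) / (nu * nv)
  arg <- min(1, max(-1, arg))
  acos(arg) * 180 / pi
}

# Coordinates of the PTM target atom for a mapped site; falls back to CB when
# the tabulated atom is unresolved, and errors when neither exists.
#' @keywords internal
site_target_atom <- function(site, s, target_atoms = target_atom_table()) {
  site <- assert_unique_mapping(site)
  at <- residue_atoms(s, site$chain_id, site$seq_num, site$icode)
  at <- heavy_atoms(at)
  if (nrow(at) == 0L) stop("mapped residue has no heavy atoms")
  hit <- target_atoms$atom[target_atoms$ptm_type == site$ptm_type &
                             target_atoms$residue == site$residue]
  name <- if (length(hit) == 1L && hit %in% at$atom_name) {
    hit
  } else if ("CB" %in% at$atom_name) {
    "CB"
  } else if ("CA" %in% at$atom_name) {
    "CA"
  } else {
    stop("no target atom, CB or CA present for site at ", site$chain_id,
         site$seq_num)
  }
  at[at$atom_name == name, , drop = FALSE][1L, ]
}

#' Side-chain orientation of one neighboring residue
#'
#' Computes the neighbor-to-site vector S_k, the neighbor's side-chain
#' direction V_k (C-alpha to functional atom) and the angle theta_k between
#' them; the neighbor is flagged functional when theta_k is strictly below
#' `theta_cutoff` degrees. Glycine neighbors have no side chain: theta is `NA`
#' and the flag is `FALSE`.
#'
#' @param site uniquely mapped site row (from [map_peptide()]).
#' @param s a `ptm_structure`.
#' @param chain_id,seq_num,icode address of the neighboring residue.
#' @param theta_cutoff functional-orientation cutoff in degrees (default 80).
#' @param functional_atoms table from [functional_atom_table()].
#' @param target_atoms table from [target_atom_table()].
#' @return one-row data.frame: neighbor address and name, `distance` (|S_k|,
#'   Angstrom), `theta` (degrees) and `is_functional`.
#' @export
orientation <- function(site, s, chain_id, seq_num, icode = "",
                        theta_cutoff = 80,
                        functional_atoms = functional_atom_table(),
                        target_atoms = target_atom_table()) {
  target <- site_target_atom(site, s, target_atoms)
  xp <- c(target$x, target$y, target$z)
  nb <- residue_atoms(s, chain_id, seq_num, icode)
  if (nrow(nb) == 0L) stop("neighbor residue not found")
  res_name <- nb$res_name[1L]
  aa <- aa_one_letter(res_name)
  ca <- nb[nb$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("neighbor residue lacks a C-alpha atom")
  xca <- c(ca$x[1L], ca$y[1L], ca$z[1L])
  s_k <- xp - xca
  dist <- sqrt(sum(s_k^2))
  out <- data.frame(
    chain_id = chain_id, seq_num = seq_num, icode = icode,
    res_name = res_name, aa = aa, distance = dist,
    theta = NA_real_, is_functional = FALSE, stringsAsFactors = FALSE
  )
  fatom <- functional_atoms[[aa]]
  if (is.null(fatom) || is.na(fatom)) return(out)   # glycine / unknown
  fa <- nb[nb$atom_name == fatom, , drop = FALSE]
  if (nrow(fa) == 0L) return(out)                   # unresolved side chain
  v_k <- c(fa$x[1L], fa$y[1L], fa$z[1L]) - xca
  out$theta <- vector_angle(s_k, v_k)
  out$is_functional <- out$theta < theta_cutoff
  out
}

#' Orientation records for all spatial neighbors of a site
#'
#' A residue is a spatial neighbor when its C-alpha lies within `radius` of the
#' site's target atom. Records are sorted by distance ascending; the substrate
#' residue itself is excluded.
#'
#' @inheritParams orientation
#' @param radius neighborhood radius in Angstrom (default 12).
#' @return data.frame of orientation records (possibly zero rows).
#' @export
functional_neighbors <- function(site, s, radius = 12,
                                 theta_cutoff = 80,
                                 functional_atoms = functional_atom_table(),
                                 target_atoms = target_atom_table()) {
  site <- assert_unique_mapping(site)
  target <- site_target_atom(site, s, target_atoms)
  xp <- matrix(c(target$x, target$y, target$z), nrow = 1L)
  a <- s$atoms
  cas <- a[protein_mask(a) & a$atom_name == "CA" &
             !(a$element %in% c("H", "D")), , drop = FALSE]
  self <- cas$chain_id == site$chain_id & cas$seq_num == site$seq_num &
    cas$icode == site$icode
  cas <- cas[!self, , drop = FALSE]
  if (nrow(cas) == 0L) return(empty_orientation_df())
  d <- as.vector(cross_distances(atom_xyz(cas), xp))
  keep <- which(d <= radius)
  if (length(keep) == 0L) return(empty_orientation_df())
  keep <- keep[order(d[keep])]
  rows <- lapply(keep, function(i) {
    orientation(site, s, cas$chain_id[i], cas$seq_num[i], cas$icode[i],
                theta_cutoff = theta_cutoff,
                functional_atoms = functional_atoms,
                target_atoms = target_atoms)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
empty_orientation_df <- function() {
  data.frame(
    chain_id = character(0), seq_num = integer(0), icode = character(0),
    res_name = character(0), aa = character(0), distance = numeric(0),
    theta = numeric(0), is_functional = logical(0), stringsAsFactors = FALSE
  )
}
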