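# Deterministic synthetic PDB fixtures: ideal helices and strands built from
# internal coordinates (NeRF chain extension), engineered two-chain contact
# interfaces, ligand complexes with an exact placement distance, and random
# coil structures for oracle tests. All builders emit PDB text so the full
# I/O path is exercised, and self-check their requested geometry before
# returning.

# ---- geometric primitives ----------------------------------------------------

#' @keywords internal
cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' @keywords internal
unit <- function(v) v / sqrt(sum(v^2))

# Natural-extension (NeRF) placement: position of atom d bonded to c, given
# bond length |cd|, angle b-c-d and dihedral a-b-c-d (degrees).
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Dihedral angle of four points in degrees
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return signed dihedral in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Rotation matrix sending unit vector u onto unit vector v (Rodrigues).
#' @keywords internal
rotation_align <- function(u, v) {
  u <- unit(u); v <- unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to u
    p <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit(cross3(u, p))
    return(2 * outer(axis, axis) - diag(3))
  }
  w <- cross3(u, v)
  wx <- matrix(c(0, -w[3L], w[2L], w[3L], 0, -w[1L], -w[2L], w[1L], 0),
               3L, 3L, byrow = TRUE)
  diag(3) + wx + wx %*% wx / (1 + c_)
}

# ---- idealized residue templates --------------------------------------------

# Side-chain internal coordinates: new atom bonded to `c`, with bond length,
# angle(b, c, new) and dihedral(a, b, c, new). Idealized bond geometry; ring
# closures are approximate but adequate for fixtures.
#' @keywords internal
side_chain_templates <- function() {
  r <- function(name, a, b, c, bond, angle, torsion) {
    list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
         torsion = torsion)
  }
  cb <- r("CB", "C", "N", "CA", 1.530, 110.5, 122.5)
  list(
    GLY = list(),
    ALA = list(cb),
    SER = list(cb, r("OG", "N", "CA", "CB", 1.417, 110.8, 180)),
    CYS = list(cb, r("SG", "N", "CA", "CB", 1.808, 113.8, 180)),
    THR = list(cb, r("OG1", "N", "CA", "CB", 1.433, 109.5, 180),
               r("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
    VAL = list(cb, r("CG1", "N", "CA", "CB", 1.521, 110.5, 180),
               r("CG2", "N", "CA", "CB", 1.521, 110.5, 60)),
    LEU = list(cb, r("CG", "N", "CA", "CB", 1.530, 116.3, 180),
               r("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
               r("CD2", "CA", "CB", "CG", 1.521, 110.7, 60)),
    ILE = list(cb, r("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
               r("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
               r("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
    MET = list(cb, r("CG", "N", "CA", "CB", 1.520, 114.0, 180),
               r("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
               r("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
    PRO = list(cb, r("CG", "N", "CA", "CB", 1.495, 104.5, 30),
               r("CD", "CA", "CB", "CG", 1.507, 106.1, -35)),
    PHE = list(cb, r("CG", "N", "CA", "CB", 1.502, 113.8, 180),
               r("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
               r("CD2", "CA", "CB", "CG", 1.384, 120.8, -90),
               r("CE1", "CB", "CG", "CD1", 1.382, 121.0, 180),
               r("CE2", "CB", "CG", "CD2", 1.382, 121.0, 180),
               r("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0)),
    TYR = list(cb, r("CG", "N", "CA", "CB", 1.502, 113.8, 180),
               r("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
               r("CD2", "CA", "CB", "CG", 1.384, 120.8, -90),
               r("CE1", "CB", "CG", "CD1", 1.382, 121.0, 180),
               r("CE2", "CB", "CG", "CD2", 1.382, 121.0, 180),
               r("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0),
               r("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
    TRP = list(cb, r("CG", "N", "CA", "CB", 1.498, 113.6, 180),
               r("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
               r("CD2", "CA", "CB", "CG", 1.433, 126.7, -90),
               r("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
               r("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
               r("CE3", "CB", "CG", "CD2", 1.398, 128.9, 0),
               r("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
               r("CZ3", "CG", "CD2", "CE3", 1.392, 118.6, 180),
               r("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
    ASP = list(cb, r("CG", "N", "CA", "CB", 1.516, 113.0, 180),
               r("OD1", "CA", "CB", "CG", 1.249, 118.5, 0),
               r("OD2", "CA", "CB", "CG", 1.249, 118.5, 180)),
    ASN = list(cb, r("CG", "N", "CA", "CB", 1.516, 112.7, 180),
               r("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
               r("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
    GLU = list(cb, r("CG", "N", "CA", "CB", 1.520, 114.0, 180),
               r("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
               r("OE1", "CB", "CG", "CD", 1.249, 118.5, 0),
               r("OE2", "CB", "CG", "CD", 1.249, 118.5, 180)),
    GLN = list(cb, r("CG", "N", "CA", "CB", 1.520, 114.0, 180),
               r("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
               r("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
               r("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
    LYS = list(cb, r("CG", "N", "CA", "CB", 1.520, 114.0, 180),
               r("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
               r("CE", "CB", "CG", "CD", 1.520, 111.3, 180),
               r("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
    ARG = list(cb, r("CG", "N", "CA", "CB", 1.520, 114.0, 180),
               r("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
               r("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
               r("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
               r("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
               r("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
    HIS = list(cb, r("CG", "N", "CA", "CB", 1.492, 113.8, 180),
               r("ND1", "CA", "CB", "CG", 1.380, 122.7, 90),
               r("CD2", "CA", "CB", "CG", 1.354, 131.0, -90),
               r("CE1", "CB", "CG", "ND1", 1.326, 109.3, 180),
               r("NE2", "CB", "CG", "CD2", 1.373, 107.2, 180))
  )
}

# ---- chain building ----------------------------------------------------------

# Build one polypeptide chain from backbone dihedrals; returns an atom
# data.frame in the parse_structure column layout.
#' @keywords internal
build_chain_atoms <- function(sequence, phi = -57, psi = -47, omega = 180,
                              chain_id = "A", start_seq = 1L) {
  aas <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aas, names(AA_1TO3))
  if (length(bad) > 0L) stop("unknown residue code(s): ",
                             paste(unique(bad), collapse = ", "))
  n <- length(aas)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  tmpl <- side_chain_templates()
  rows <- list()
  add <- function(res_i, res3, name, xyz) {
    el <- substr(gsub("[0-9]", "", name), 1L, 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      record = "ATOM", serial = length(rows) + 1L, atom_name = name,
      altloc = "", res_name = res3, chain_id = chain_id,
      seq_num = start_seq + res_i - 1L, icode = "",
      x = xyz[1L], y = xyz[2L], z = xyz[3L], occupancy = 1.0, bfactor = 0.0,
      element = el, is_hetero = FALSE, stringsAsFactors = FALSE
    )
  }
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    res3 <- AA_1TO3[[aas[i]]]
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      ang <- 111.2 * pi / 180
      C <- CA + 1.525 * c(-cos(ang), sin(ang), 0)
    } else {
      N <- place_atom(prevN, prevCA, prevC, 1.329, 116.2, psi[i - 1L])
      CA <- place_atom(prevCA, prevC, N, 1.458, 121.7, omega[i])
      C <- place_atom(prevC, N, CA, 1.525, 111.2, phi[i])
    }
    O <- place_atom(N, CA, C, 1.231, 120.5, psi[i] + 180)
    add(i, res3, "N", N); add(i, res3, "CA", CA); add(i, res3, "C", C)
    add(i, res3, "O", O)
    placed <- list(N = N, CA = CA, C = C, O = O)
    for (t in tmpl[[res3]]) {
      xyz <- place_atom(placed[[t$a]], placed[[t$b]], placed[[t$c]],
                        t$bond, t$angle, t$torsion)
      placed[[t$name]] <- xyz
      add(i, res3, t$name, xyz)
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
atoms_to_pdb_text <- function(atoms, structure_id = "SYN1", resolution = 2.0,
                              experiment = "X-RAY DIFFRACTION") {
  atoms$x <- round(atoms$x, 3L)
  atoms$y <- round(atoms$y, 3L)
  atoms$z <- round(atoms$z, 3L)
  s <- structure(list(structure_id = structure_id, atoms = atoms,
                      resolution = resolution, experiment = experiment),
                 class = "ptm_structure")
  write_structure(s)
}

#' Build an ideal alpha-helix
#'
#' A single chain with ideal helical backbone dihedrals (phi = -57,
#' psi = -47, omega = 180 degrees) and idealized side chains.
#'
#' @param n number of residues (>= 6).
#' @param sequence one-letter sequence of length `n`; defaults to a cyclic
#'   proline-free sweep of the amino-acid alphabet.
#' @param chain_id chain identifier.
#' @param resolution nominal resolution stamped in the REMARK 2 header.
#' @param structure_id id string.
#' @return PDB-format text.
#' @export
#' @examples
#' s <- parse_structure(build_helix(n = 10))
#' nrow(residue_table(s))
build_helix <- function(n = 20L, sequence = NULL, chain_id = "A",
                        resolution = 2.0, structure_id = "HLX1") {
  if (n < 6L) stop("a helix fixture needs at least 6 residues")
  if (is.null(sequence)) sequence <- default_sequence(n)
  stopifnot(nchar(sequence) == n)
  atoms <- build_chain_atoms(sequence, phi = -57, psi = -47,
                             chain_id = chain_id)
  atoms_to_pdb_text(atoms, structure_id = structure_id,
                    resolution = resolution)
}

# Proline-free cyclic sweep of the standard alphabet (P would interrupt the
# helix hydrogen-bond donor pattern).
#' @keywords internal
default_sequence <- function(n) {
  base <- "ACDEFGHIKLMNQRSTVWY"
  paste(strsplit(strrep(base, ceiling(n / nchar(base))), "")[[1]][seq_len(n)],
        collapse = "")
}

#' Build an isolated extended strand
#'
#' Single chain in an extended beta conformation (phi = -139, psi = 135); with
#' no pairing partner its residues are assigned coil.
#'
#' @inheritParams build_helix
#' @return PDB-format text.
#' @export
build_strand <- function(n = 10L, sequence = NULL, chain_id = "A",
                         resolution = 2.0, structure_id = "STR1") {
  if (n < 3L) stop("a strand fixture needs at least 3 residues")
  if (is.null(sequence)) sequence <- default_sequence(n)
  stopifnot(nchar(sequence) == n)
  atoms <- build_chain_atoms(sequence, phi = -139, psi = 135,
                             chain_id = chain_id)
  atoms_to_pdb_text(atoms, structure_id = structure_id,
                    resolution = resolution)
}

#' Build an antiparallel two-strand sheet pair
#'
#' Two extended chains (A and B); chain B is a 180-degree in-plane rotation of
#' chain A, translated to the inter-strand offset that maximizes the number of
#' Kabsch-Sander backbone hydrogen bonds (deterministic grid search). The
#' builder fails if the paired placement does not yield strand (E) residues.
#'
#' @param n residues per strand.
#' @param sequence sequence per strand (default poly-valine-free sweep).
#' @param resolution,structure_id metadata.
#' @return PDB-format text.
#' @export
build_sheet_pair <- function(n = 8L, sequence = NULL, resolution = 2.0,
                             structure_id = "SHT1") {
  if (n < 5L) stop("a sheet-pair fixture needs at least 5 residues per strand")
  if (is.null(sequence)) sequence <- strrep("A", n)
  a <- build_chain_atoms(sequence, phi = -139, psi = 135, chain_id = "A")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # principal strand axis -> x; sheet normal -> z
  ctr <- colMeans(xyz)
  cas <- xyz[a$atom_name == "CA", , drop = FALSE]
  ax <- unit(cas[nrow(cas), ] - cas[1L, ])
  R1 <- rotation_align(ax, c(1, 0, 0))
  xyz <- sweep(xyz, 2L, ctr) %*% t(R1)
  a[, c("x", "y", "z")] <- xyz
  flip <- diag(c(-1, 1, -1))  # 180 degrees about the y axis
  best <- NULL
  for (dy in seq(4.2, 5.6, by = 0.2)) {
    for (dx in seq(-2, 2, by = 0.25)) {
      b <- a
      bxyz <- xyz %*% t(flip)
      bxyz[, 1L] <- bxyz[, 1L] + dx
      bxyz[, 2L] <- bxyz[, 2L] + dy
      b[, c("x", "y", "z")] <- bxyz
      b$chain_id <- "B"
      cand <- rbind(a, b)
      s <- structure(list(structure_id = structure_id, atoms = cand,
                          resolution = resolution,
                          experiment = "X-RAY DIFFRACTION"),
                     class = "ptm_structure")
      ss <- secondary_structure(s)
      ne <- sum(ss$ss == "E")
      if (is.null(best) || ne > best$ne) best <- list(ne = ne, atoms = cand)
    }
  }
  if (best$ne < 4L) {
    stop("sheet-pair construction failed: no paired strand geometry found")
  }
  atoms_to_pdb_text(best$atoms, structure_id = structure_id,
                    resolution = resolution)
}

# ---- engineered interfaces ---------------------------------------------------

# Build a one-residue arm and rigidly place it so `atom` sits at `point` with
# the CA->atom direction along `direction`.
#' @keywords internal
place_residue_arm <- function(aa, atom, point, direction, chain_id, seq_num) {
  at <- build_chain_atoms(aa, phi = -139, psi = 135, chain_id = chain_id,
                          start_seq = seq_num)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ca <- xyz[at$atom_name == "CA", ][1:3]
  q <- xyz[at$atom_name == atom, ]
  if (is.matrix(q)) q <- q[1L, ]
  if (length(q) != 3L) stop("contact atom ", atom, " absent from residue ", aa)
  direction <- unit(direction)
  R <- rotation_align(q - ca, direction)
  xyz <- sweep(xyz, 2L, ca) %*% t(R)
  arm <- sqrt(sum((q - ca)^2))
  shift <- point - direction * arm
  xyz <- sweep(xyz, 2L, shift, "+")
  at[, c("x", "y", "z")] <- xyz
  at
}

#' Build a two-chain structure with engineered residue contacts
#'
#' Places one residue pair per request: the pair's designated contact atoms sit
#' exactly `distance` apart, facing each other, with successive pairs spaced
#' far apart (30 A) so that no unrequested cross-chain contact arises. Kinds:
#' `"vdw"` (Ala CB vs Ala CB), `"hbond"` (Lys NZ vs Gly backbone O) and
#' `"salt_bridge"` (Lys NZ vs Glu OE1). After building, the geometry is
#' verified by a brute-force contact scan against the request; an infeasible
#' or dirty construction errors.
#'
#' @param pairs data.frame with columns `kind` and `distance` (Angstrom), one
#'   row per requested residue pair.
#' @param resolution,structure_id metadata.
#' @return PDB-format text (chains A and B, residue i of each chain forming
#'   requested pair i).
#' @export
#' @examples
#' pdb <- build_interface(data.frame(kind = "salt_bridge", distance = 5.4))
build_interface <- function(pairs, resolution = 2.0, structure_id = "IFC1") {
  stopifnot(is.data.frame(pairs), all(c("kind", "distance") %in% names(pairs)),
            nrow(pairs) >= 1L, all(pairs$distance > 0))
  recipes <- list(
    vdw = list(a = c("A", "CB"), b = c("A", "CB")),
    hbond = list(a = c("K", "NZ"), b = c("G", "O")),
    salt_bridge = list(a = c("K", "NZ"), b = c("E", "OE1"))
  )
  bad <- setdiff(pairs$kind, names(recipes))
  if (length(bad) > 0L) stop("unknown contact kind(s): ",
                             paste(unique(bad), collapse = ", "))
  rows_a <- list(); rows_b <- list()
  for (i in seq_len(nrow(pairs))) {
    rc <- recipes[[pairs$kind[i]]]
    y <- 30 * (i - 1L)
    d <- pairs$distance[i]
    rows_a[[i]] <- place_residue_arm(rc$a[1L], rc$a[2L], c(0, y, 0),
                                     c(1, 0, 0), "A", i)
    rows_b[[i]] <- place_residue_arm(rc$b[1L], rc$b[2L], c(d, y, 0),
                                     c(-1, 0, 0), "B", i)
  }
  atoms <- rbind(do.call(rbind, rows_a), do.call(rbind, rows_b))
  text <- atoms_to_pdb_text(atoms, structure_id = structure_id,
                            resolution = resolution)
  # post-build self-check against the request
  s <- parse_structure(text)
  nres <- nrow(pairs)
  dom_a <- domain_range("A", 1L, nres, "domA")
  dom_b <- domain_range("B", 1L, nres, "domB")
  got <- detect_contacts(s, dom_a, dom_b, method = "brute")
  cutoffs <- c(vdw = 5.0, hbond = 3.5, salt_bridge = 5.5)
  want <- pairs[pairs$distance <= cutoffs[pairs$kind], , drop = FALSE]
  want_idx <- which(pairs$distance <= cutoffs[pairs$kind])
  ok <- nrow(got) == length(want_idx) &&
    all(got$seq_a == got$seq_b) &&
    setequal(got$seq_a, want_idx) &&
    all(got$kind[order(got$seq_a)] ==
          pairs$kind[sort(want_idx)]) &&
    all(abs(got$distance - pairs$distance[got$seq_a]) < 0.02)
  if (!ok) {
    stop("interface construction failed its post-build contact check")
  }
  text
}

# ---- ligand complex ----------------------------------------------------------

#' Build a helix with a small-molecule ligand at a chosen distance
#'
#' The ligand (het code `het`, three heavy atoms) is placed along the outward
#' direction of the site residue's side chain so that the minimum distance
#' between the site's side-chain heavy atoms and the ligand heavy atoms equals
#' `distance` within 0.01 A (verified; errors otherwise).
#'
#' @param distance requested minimum side-chain-to-ligand distance (Angstrom).
#' @param n helix length; the site residue is a serine placed at `site_pos`.
#' @param site_pos residue position of the serine site (default centre).
#' @param het ligand het code (default `"LIG"`).
#' @param resolution,structure_id metadata.
#' @return PDB-format text.
#' @export
build_ligand_complex <- function(distance, n = 12L, site_pos = 6L,
                                 het = "LIG", resolution = 2.0,
                                 structure_id = "LIG1") {
  stopifnot(distance > 0, site_pos >= 1L, site_pos <= n)
  seqn <- default_sequence(n)
  substr(seqn, site_pos, site_pos) <- "S"
  atoms <- build_chain_atoms(seqn, phi = -57, psi = -47, chain_id = "A")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  site_rows <- atoms$seq_num == site_pos
  og <- xyz[site_rows & atoms$atom_name == "OG", ]
  ctr <- colMeans(xyz[atoms$atom_name == "CA", , drop = FALSE])
  u <- unit(og - ctr)
  sc <- xyz[site_rows & !(atoms$atom_name %in% BACKBONE_ATOMS), ,
            drop = FALSE]
  lig_local <- rbind(c(0, 0, 0), c(1.5, 0.4, 0), c(3.0, 0, 0.4))
  lig_names <- c("C1", "C2", "O1")
  lig_el <- c("C", "C", "O")
  base <- og + u * distance
  lig <- sweep(lig_local %*% t(rotation_align(c(1, 0, 0), u)), 2L, base, "+")
  # exact placement: shift along u until the minimum measured on PDB-rounded
  # coordinates lies in [distance - 0.002, distance], so that an inclusive
  # cutoff equal to `distance` is genuinely attained
  sc3 <- round(sc, 3L)
  target <- distance - 0.001
  for (k in 1:50) {
    m <- min(cross_distances(sc3, round(lig, 3L)))
    if (m <= distance && m >= distance - 0.002) break
    lig <- sweep(lig, 2L, u * (target - m), "+")
  }
  m2 <- min(cross_distances(sc3, round(lig, 3L)))
  if (m2 > distance || m2 < distance - 0.002) {
    stop("ligand placement infeasible: achieved ", round(m2, 4),
         " A for requested ", distance, " A")
  }
  lig <- round(lig, 3L)
  lig_rows <- data.frame(
    record = "HETATM", serial = nrow(atoms) + seq_len(3L),
    atom_name = lig_names, altloc = "", res_name = het, chain_id = "A",
    seq_num = 900L, icode = "", x = lig[, 1L], y = lig[, 2L], z = lig[, 3L],
    occupancy = 1.0, bfactor = 0.0, element = lig_el, is_hetero = TRUE,
    stringsAsFactors = FALSE
  )
  atoms_to_pdb_text(rbind(atoms, lig_rows), structure_id = structure_id,
                    resolution = resolution)
}

# ---- random structures -------------------------------------------------------

#' Build a random-coil chain
#'
#' A self-avoiding random walk of residues (3.8 A C-alpha steps) with jittered
#' N, C and O atoms, for property-based oracle tests. Deterministic for a
#' given seed; the global RNG state is preserved.
#'
#' @param n number of residues.
#' @param seed integer seed (default 7).
#' @param chain_id chain identifier.
#' @param origin 3-vector offset of the first residue.
#' @param resolution,structure_id metadata.
#' @return PDB-format text.
#' @export
build_random_coil <- function(n = 30L, seed = 7L, chain_id = "A",
                              origin = c(0, 0, 0), resolution = 2.0,
                              structure_id = "RND1") {
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rdir <- function() unit(stats::rnorm(3L))
  cas <- matrix(NA_real_, n, 3L)
  cas[1L, ] <- origin
  for (i in seq_len(n)[-1L]) {
    repeat {
      cand <- cas[i - 1L, ] + 3.8 * rdir()
      prior <- cas[seq_len(i - 1L), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prior, 2L, cand)^2))) > 3.5) break
    }
    cas[i, ] <- cand
  }
  res3 <- sample(names(AA_3TO1), n, replace = TRUE)
  rows <- list()
  for (i in seq_len(n)) {
    npos <- cas[i, ] + 1.46 * rdir()
    cpos <- cas[i, ] + 1.53 * rdir()
    opos <- cpos + 1.23 * rdir()
    for (at in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
      xyz <- switch(at[1L], N = npos, CA = cas[i, ], C = cpos, O = opos)
      rows[[length(rows) + 1L]] <- data.frame(
        record = "ATOM", serial = length(rows) + 1L, atom_name = at[1L],
        altloc = "", res_name = res3[i], chain_id = chain_id, seq_num = i,
        icode = "", x = xyz[1L], y = xyz[2L], z = xyz[3L], occupancy = 1.0,
        bfactor = 0.0, element = at[2L], is_hetero = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  atoms_to_pdb_text(do.call(rbind, rows), structure_id = structure_id,
                    resolution = resolution)
}

# ---- PTM-site tables ---------------------------------------------------------

#' Build a PTM-site TSV for chosen residues of a structure
#'
#' Emits peptide windows read directly from the chain's coordinate-derived
#' sequence, so mapping back is exact by construction. Variants deliberately
#' break this: `"mismatch"` mutates one flanking residue (mapping must fail)
#' and `"repeat"` leaves the window untouched for use on repetitive chains
#' (mapping must be ambiguous).
#'
#' @param pdb_text PDB text of the structure the sites live on.
#' @param chain_id chain carrying the sites.
#' @param positions residue positions (1-based index along the chain, which
#'   for fixture chains equals the author residue number).
#' @param ptm_types modification type per site (recycled).
#' @param protein_id protein identifier used in the table.
#' @param window_half half-window (default 10; windows truncate at termini).
#' @param variant `"exact"` (default), `"mismatch"` or `"repeat"`.
#' @return TSV text with header protein_id, position, ptm_type, residue,
#'   peptide, window_half.
#' @export
build_ptm_table <- function(pdb_text, chain_id = "A", positions,
                            ptm_types = "phosphorylation",
                            protein_id = "FIXP1", window_half = 10L,
                            variant = c("exact", "mismatch", "repeat")) {
  variant <- match.arg(variant)
  s <- parse_structure(pdb_text)
  cs <- chain_sequence(s, chain_id)
  ptm_types <- rep_len(ptm_types, length(positions))
  lines <- "protein_id\tposition\tptm_type\tresidue\tpeptide\twindow_half"
  for (k in seq_along(positions)) {
    pos <- positions[k]
    if (pos < 1L || pos > nchar(cs$sequence)) {
      stop("position ", pos, " outside chain")
    }
    lo <- max(1L, pos - window_half)
    hi <- min(nchar(cs$sequence), pos + window_half)
    pep <- substr(cs$sequence, lo, hi)
    res <- substr(cs$sequence, pos, pos)
    if (variant == "mismatch") {
      j <- if (pos - lo >= 1L) 1L else nchar(pep)
      orig <- substr(pep, j, j)
      repl <- if (orig == "W") "Y" else "W"
      substr(pep, j, j) <- repl
    }
    lines <- c(lines, paste(protein_id, pos, ptm_types[k], res, pep,
                            window_half, sep = "\t"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
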