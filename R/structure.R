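# Fixed-column PDB (v3.3) structure container and primitives.
#
# A `ptm_structure` holds a flat atom table (one row per ATOM/HETATM record
# after altloc resolution) plus file-level metadata. Residues are addressed by
# author numbering: (chain_id, seq_num, icode).

#' Parse PDB-format text into a structure object
#'
#' Reads fixed-column ATOM/HETATM records, the `REMARK   2 RESOLUTION` line and
#' the `EXPDTA` method line. Alternate locations are resolved to a single
#' conformer (blank or 'A' preferred, else highest occupancy); for multi-model
#' (NMR) files only the first model is kept. Hydrogens are retained in the atom
#' table but are ignored by every distance-based computation in the package.
#'
#' @param text character scalar (or vector of lines) of PDB-format content.
#' @param structure_id optional identifier; defaults to the HEADER id code or
#'   `"UNKNOWN"`.
#' @return an object of class `ptm_structure`: a list with `structure_id`,
#'   `atoms` (data.frame with columns record, serial, atom_name, altloc,
#'   res_name, chain_id, seq_num, icode, x, y, z, occupancy, bfactor, element,
#'   is_hetero), `resolution` (Angstrom or `NA`) and `experiment`.
#' @export
#' @examples
#' s <- parse_structure(build_helix(n = 8))
#' s
parse_structure <- function(text, structure_id = NULL) {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  if (length(lines) == 0L) stop("empty input: no PDB records found")

  rec6 <- substr(lines, 1L, 6L)
  is_atom <- rec6 == "ATOM  " | rec6 == "HETATM"
  if (!any(is_atom)) stop("empty input: no ATOM or HETATM records found")

  # First model only
  model_starts <- which(substr(lines, 1L, 5L) == "MODEL")
  if (length(model_starts) > 1L) {
    endmdl <- which(substr(lines, 1L, 6L) == "ENDMDL")
    first_end <- endmdl[endmdl > model_starts[1L]][1L]
    if (!is.na(first_end)) is_atom[seq_along(lines) > first_end] <- FALSE
  }

  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2) > 0L) {
    m <- regmatches(rem2[1L], regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)",
                                      rem2[1L], perl = TRUE))
    if (length(m) == 1L) resolution <- as.numeric(m)
  }
  experiment <- NA_character_
  expdta <- grep("^EXPDTA", lines, value = TRUE)
  if (length(expdta) > 0L) {
    experiment <- trimws(substr(expdta[1L], 11L, nchar(expdta[1L])))
  }
  if (is.null(structure_id)) {
    header <- grep("^HEADER", lines, value = TRUE)
    structure_id <- if (length(header) > 0L && nchar(header[1L]) >= 66L) {
      trimws(substr(header[1L], 63L, 66L))
    } else ""
    if (identical(structure_id, "")) structure_id <- "UNKNOWN"
  }

  idx <- which(is_atom)
  ln <- lines[idx]
  width <- nchar(ln)
  if (any(width < 54L)) {
    bad <- idx[which(width < 54L)[1L]]
    stop("malformed ATOM/HETATM record (truncated before coordinates) at line ",
         bad)
  }
  num <- function(from, to, what) {
    raw <- trimws(substr(ln, from, to))
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(out) & raw != "")
    if (length(bad) > 0L) {
      stop("malformed ", what, " field in ATOM/HETATM record at line ",
           idx[bad[1L]])
    }
    out
  }
  x <- num(31L, 38L, "x coordinate")
  y <- num(39L, 46L, "y coordinate")
  z <- num(47L, 54L, "z coordinate")
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    bad <- idx[which(is.na(x) | is.na(y) | is.na(z))[1L]]
    stop("malformed coordinate field (blank) at line ", bad)
  }
  seq_num <- suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L))))
  if (any(is.na(seq_num))) {
    stop("malformed residue number at line ", idx[which(is.na(seq_num))[1L]])
  }
  occupancy <- num(55L, 60L, "occupancy")
  occupancy[is.na(occupancy)] <- 1.0
  bfactor <- num(61L, 66L, "B-factor")
  bfactor[is.na(bfactor)] <- 0.0

  atom_name <- trimws(substr(ln, 13L, 16L))
  element <- toupper(trimws(substr(ln, 77L, 78L)))
  element[is.na(element)] <- ""
  guess <- element == ""
  if (any(guess)) {
    element[guess] <- guess_element(atom_name[guess])
  }
  if (any(element == "")) {
    stop("cannot determine element for atom record at line ",
         idx[which(element == "")[1L]])
  }

  atoms <- data.frame(
    record = trimws(rec6[idx]),
    serial = suppressWarnings(as.integer(trimws(substr(ln, 7L, 11L)))),
    atom_name = atom_name,
    altloc = substr(ln, 17L, 17L),
    res_name = trimws(substr(ln, 18L, 20L)),
    chain_id = substr(ln, 22L, 22L),
    seq_num = seq_num,
    icode = gsub(" ", "", substr(ln, 27L, 27L), fixed = TRUE),
    x = x, y = y, z = z,
    occupancy = occupancy, bfactor = bfactor,
    element = element,
    is_hetero = trimws(rec6[idx]) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$altloc <- gsub(" ", "", atoms$altloc, fixed = TRUE)
  atoms <- resolve_altlocs(atoms)
  rownames(atoms) <- NULL

  structure(
    list(structure_id = structure_id, atoms = atoms,
         resolution = resolution, experiment = experiment),
    class = "ptm_structure"
  )
}

#' Read a structure from a PDB file
#'
#' @param path path to a PDB-format file.
#' @inheritParams parse_structure
#' @return a `ptm_structure`.
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  parse_structure(readLines(path, warn = FALSE), structure_id = structure_id)
}

# Keep altloc blank/'A' when present within an (residue, atom name) group,
# otherwise the highest-occupancy conformer; deterministic first-wins ties.
#' @keywords internal
resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain_id, atoms$seq_num, atoms$icode, atoms$atom_name,
               sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (grp in split(seq_len(nrow(atoms)), key)) {
    if (length(grp) == 1L) next
    alt <- atoms$altloc[grp]
    pref <- grp[alt %in% c("", "A")]
    chosen <- if (length(pref) > 0L) {
      pref[1L]
    } else {
      grp[which.max(atoms$occupancy[grp])]
    }
    keep[setdiff(grp, chosen)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' @keywords internal
guess_element <- function(atom_name) {
  two <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "SE", "CU", "NI",
           "CO", "CD", "HG")
  nm <- gsub("[0-9']", "", toupper(atom_name))
  out <- substr(nm, 1L, 1L)
  # Names like "FE" in HETATM metal records; protein "CA" is calcium only when
  # the full stripped name is exactly a metal symbol AND starts in column 13
  # (we cannot see columns here, so protein CA/CB/... take priority).
  metal <- nm %in% two & !(nm %in% c("CA", "CB", "CD", "CE", "CG", "CL", "NA"))
  out[metal] <- nm[metal]
  out[substr(nm, 1L, 1L) == "H" | grepl("^[0-9]*H", toupper(atom_name))] <- "H"
  out
}

#' Write a structure as PDB-format text
#'
#' Emits REMARK 2 / EXPDTA metadata when present, fixed-column ATOM/HETATM
#' records, TER records at protein chain ends and END. The output round-trips
#' through [parse_structure()] with identical identifiers and coordinates.
#'
#' @param s a `ptm_structure`.
#' @param path optional file path; when given, text is also written there.
#' @return the PDB text, invisibly when `path` is given.
#' @export
write_structure <- function(s, path = NULL) {
  stopifnot(inherits(s, "ptm_structure"))
  a <- s$atoms
  out <- character(0)
  if (!is.na(s$structure_id) && !identical(s$structure_id, "UNKNOWN")) {
    out <- c(out, sprintf("HEADER    %-40s%-9s   %-4s", "SYNTHETIC STRUCTURE",
                          "01-JAN-26", substr(s$structure_id, 1L, 4L)))
  }
  if (!is.na(s$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          s$resolution))
  } else if (!is.na(s$experiment) && grepl("NMR", s$experiment)) {
    out <- c(out, "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  }
  if (!is.na(s$experiment)) out <- c(out, sprintf("EXPDTA    %s", s$experiment))

  fmt_name <- function(name, element) {
    ifelse(nchar(name) >= 4L, substr(paste0(name, "   "), 1L, 4L),
           ifelse(nchar(element) == 1L,
                  sprintf(" %-3s", name), sprintf("%-4s", name)))
  }
  rec <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$is_hetero, "HETATM", "ATOM"),
    seq_len(nrow(a)),
    fmt_name(a$atom_name, a$element),
    substr(paste0(a$altloc, " "), 1L, 1L),
    a$res_name,
    ifelse(a$chain_id == "", " ", a$chain_id),
    a$seq_num,
    substr(paste0(a$icode, " "), 1L, 1L),
    a$x, a$y, a$z, a$occupancy, a$bfactor,
    substr(paste0(a$element, " "), 1L, 2L)
  )
  # TER after the last protein atom of each chain
  lines <- character(0)
  for (ch in unique(a$chain_id)) {
    rows <- which(a$chain_id == ch)
    lines <- c(lines, rec[rows])
    if (any(!a$is_hetero[rows])) lines <- c(lines, "TER")
  }
  out <- c(out, lines, "END")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

#' @export
print.ptm_structure <- function(x, ...) {
  a <- x$atoms
  prot <- !a$is_hetero & !(a$res_name %in% WATER_CODES)
  cat(sprintf("ptm_structure '%s'\n", x$structure_id))
  cat(sprintf("  chains: %s\n",
              paste(sort(unique(a$chain_id)), collapse = ", ")))
  cat(sprintf("  atoms: %d (%d hetero), residues: %d\n", nrow(a),
              sum(a$is_hetero),
              nrow(unique(a[prot, c("chain_id", "seq_num", "icode")]))))
  cat(sprintf("  resolution: %s, experiment: %s\n",
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              ifelse(is.na(x$experiment), "NA", x$experiment)))
  invisible(x)
}

#' Resolution / experiment filter
#'
#' Accepts structures whose crystallographic resolution is strictly below the
#' cutoff, and NMR structures (which carry no resolution).
#'
#' @param s a `ptm_structure`.
#' @param cutoff resolution cutoff in Angstrom (default 2.5).
#' @return logical flag.
#' @export
passes_resolution_filter <- function(s, cutoff = 2.5) {
  stopifnot(inherits(s, "ptm_structure"), cutoff > 0)
  if (!is.na(s$experiment) && grepl("NMR", s$experiment, ignore.case = TRUE)) {
    return(TRUE)
  }
  !is.na(s$resolution) && s$resolution < cutoff
}

# ---- residue-level accessors -------------------------------------------------

#' @keywords internal
protein_mask <- function(atoms) {
  !(atoms$res_name %in% WATER_CODES) & is_standard_or_modified_aa(atoms$res_name)
}

#' Table of residues in a structure
#'
#' @param s a `ptm_structure`.
#' @param protein_only drop waters and non amino-acid heteros (default TRUE).
#' @return data.frame with chain_id, seq_num, icode, res_name, aa (one-letter),
#'   is_hetero, in file order.
#' @export
residue_table <- function(s, protein_only = TRUE) {
  a <- s$atoms
  if (protein_only) a <- a[protein_mask(a), , drop = FALSE]
  key <- paste(a$chain_id, a$seq_num, a$icode, sep = "\r")
  first <- !duplicated(key)
  out <- a[first, c("chain_id", "seq_num", "icode", "res_name", "is_hetero")]
  out$aa <- aa_one_letter(out$res_name)
  rownames(out) <- NULL
  out
}

#' Atoms of one residue
#'
#' @param s a `ptm_structure`.
#' @param chain_id,seq_num,icode author-numbering residue address.
#' @return data.frame of atom rows (possibly empty).
#' @export
residue_atoms <- function(s, chain_id, seq_num, icode = "") {
  a <- s$atoms
  a[a$chain_id == chain_id & a$seq_num == seq_num & a$icode == icode, ,
    drop = FALSE]
}

#' @keywords internal
heavy_atoms <- function(atoms) {
  atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
}

#' @keywords internal
atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Minimum heavy-atom distance between two atom sets
#'
#' @param a,b atom data.frames (e.g. from [residue_atoms()]) or ligand atom
#'   tables; hydrogens are excluded.
#' @return minimum Euclidean distance in Angstrom.
#' @export
min_heavy_distance <- function(a, b) {
  ha <- heavy_atoms(a)
  hb <- heavy_atoms(b)
  if (nrow(ha) == 0L || nrow(hb) == 0L) {
    stop("min_heavy_distance: residue has no heavy atoms")
  }
  min(cross_distances(atom_xyz(ha), atom_xyz(hb)))
}

#' @keywords internal
cross_distances <- function(m1, m2) {
  # |m1| x |m2| Euclidean distance matrix
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * tcrossprod(m1, m2)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' One-letter sequence of a chain with a position map
#'
#' The sequence is derived from coordinate (ATOM) records in author order, so
#' unresolved residues are absent; modified residues are translated to their
#' parent code (SEP to S, TPO to T, PTR to Y, ...) and unknown residues to X.
#'
#' @param s a `ptm_structure`.
#' @param chain_id single-character chain identifier.
#' @return list with `sequence` (character scalar) and `map` (data.frame of
#'   pos, seq_num, icode, res_name, aa) such that sequence index i corresponds
#'   to map row i; the map is invertible in both directions.
#' @export
chain_sequence <- function(s, chain_id) {
  rt <- residue_table(s)
  rt <- rt[rt$chain_id == chain_id, , drop = FALSE]
  if (nrow(rt) == 0L) {
    stop("chain ", chain_id, " has no amino-acid residues")
  }
  rt$pos <- seq_len(nrow(rt))
  list(
    sequence = paste(rt$aa, collapse = ""),
    map = rt[, c("pos", "seq_num", "icode", "res_name", "aa")]
  )
}
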