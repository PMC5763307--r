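# Shared fixture construction for the test suite. Everything is generated in
# code at test time; nothing is read from disk except files the tests write.

# A fake uniquely mapped site row, for functions that only need the mapped
# address (chain, residue) plus PTM metadata.
fake_mapped_site <- function(chain_id = "A", seq_num = 1L, icode = "",
                             ptm_type = "phosphorylation", residue = "S",
                             position = seq_num) {
  data.frame(
    protein_id = "TESTP", position = as.integer(position),
    ptm_type = ptm_type, residue = residue,
    peptide = strrep(residue, 5L), window_half = 2L,
    structure_id = "TEST", chain_id = chain_id,
    seq_num = as.integer(seq_num), icode = icode,
    match_kind = "unique", stringsAsFactors = FALSE
  )
}

# Hand-written PDB ATOM line (fixed columns).
atom_line <- function(serial, name, res, chain, seq, x, y, z,
                      element = substr(name, 1, 1), het = FALSE,
                      altloc = " ", occ = 1.0) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) >= 4) substr(paste0(name, "   "), 1, 4) else
            sprintf(" %-3s", name),
          altloc, res, chain, seq, x, y, z, occ, 0.0, element)
}

# Structure from a list of atom_line() strings plus optional header lines.
pdb_from_lines <- function(..., header = character(0)) {
  parse_structure(c(header, ...))
}

# Apply a deterministic rigid transform (rotation + translation) to all atoms.
rigid_transform <- function(s, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  s$atoms[, c("x", "y", "z")] <- xyz
  s
}

# Two-chain random structure for neighbor-search oracle tests.
random_two_chain <- function(seed, n = 25L) {
  a <- parse_structure(build_random_coil(n = n, seed = seed, chain_id = "A"))
  b <- parse_structure(build_random_coil(n = n, seed = seed + 1000L,
                                         chain_id = "B",
                                         origin = c(6, 0, 0)))
  b$atoms$chain_id <- "B"
  a$atoms <- rbind(a$atoms, b$atoms)
  a
}

# Full pipeline bundle: helix chain A with a phospho-site and a nearby ligand,
# plus chain B (a translated copy of chain A) forming an interface. Returns
# the file paths run_characterize() needs.
make_bundle <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- build_ligand_complex(6.4, n = 12L, site_pos = 6L)
  s <- parse_structure(txt)
  prot <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
  b <- prot
  b$chain_id <- "B"
  # translate chain B to sit alongside chain A
  b$y <- b$y + 9.5
  s$atoms <- rbind(s$atoms, b)
  pdb <- file.path(dir, "bundle.pdb")
  write_structure(s, pdb)
  sites <- file.path(dir, "sites.tsv")
  writeLines(sub("\n$", "", build_ptm_table(write_structure(s), "A",
                                            positions = c(6L, 9L),
                                            ptm_types = c("phosphorylation",
                                                          "acetylation"),
                                            window_half = 4L)), sites)
  domains <- file.path(dir, "domains.tsv")
  writeLines(c("chain_id\tstart\tend\tdomain_name",
               "A\t1\t12\tdomA", "B\t1\t12\tdomB"), domains)
  ligands <- file.path(dir, "ligands.tsv")
  writeLines(c("het_code\tdrug_name\tdrug_id",
               "LIG\ttestdrugin\tDB99999"), ligands)
  list(pdb = pdb, sites = sites, domains = domains, ligands = ligands)
}
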