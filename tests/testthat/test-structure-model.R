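# PDB parsing, metadata capture, sequence extraction and distance primitives.

test_that("minimal and fixture structures parse with every record represented", {
  s <- pdb_from_lines(atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3))
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unique(s$atoms$chain_id), "A")
  expect_equal(nrow(residue_table(s)), 1L)
  expect_equal(s$atoms$x, 1)

  h <- parse_structure(build_helix(n = 20))
  rt <- residue_table(h)
  expect_equal(nrow(rt), 20L)
  expect_equal(unique(rt$chain_id), "A")
})

test_that("REMARK 2 resolution and EXPDTA are captured", {
  s <- pdb_from_lines(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    header = "REMARK   2 RESOLUTION.    2.30 ANGSTROMS."
  )
  expect_equal(s$resolution, 2.30)
  nmr <- pdb_from_lines(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    header = c("EXPDTA    SOLUTION NMR")
  )
  expect_true(is.na(nmr$resolution))
  expect_match(nmr$experiment, "NMR")
})

test_that("resolution filter is strict and admits NMR models", {
  ok <- pdb_from_lines(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                       header = "REMARK   2 RESOLUTION.    2.30 ANGSTROMS.")
  at <- pdb_from_lines(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                       header = "REMARK   2 RESOLUTION.    2.50 ANGSTROMS.")
  nmr <- pdb_from_lines(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                        header = "EXPDTA    SOLUTION NMR")
  none <- pdb_from_lines(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0))
  expect_true(passes_resolution_filter(ok, 2.5))
  expect_false(passes_resolution_filter(at, 2.5))   # strictly below
  expect_true(passes_resolution_filter(nmr, 2.5))
  expect_false(passes_resolution_filter(none, 2.5))
})

test_that("malformed records and empty input produce line-numbered errors", {
  bad <- c("REMARK   2 RESOLUTION.    2.00 ANGSTROMS.",
           atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           "ATOM      2  CA  ALA A   2      bad.000   0.000   0.000")
  expect_error(parse_structure(bad), "line 3")
  expect_error(parse_structure("TITLE     NOTHING HERE"), "empty|no ATOM")
  expect_error(parse_structure(character(0)), "empty")
})

test_that("altloc resolution keeps blank/'A' then highest occupancy", {
  s <- pdb_from_lines(
    atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, altloc = "A", occ = 0.4),
    atom_line(2, "CA", "SER", "A", 1, 9, 9, 9, altloc = "B", occ = 0.6),
    atom_line(3, "OG", "SER", "A", 1, 1, 1, 1, altloc = "B", occ = 0.7),
    atom_line(4, "OG", "SER", "A", 1, 2, 2, 2, altloc = "C", occ = 0.3)
  )
  expect_equal(nrow(s$atoms), 2L)
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  expect_equal(ca$altloc, "A")          # blank/'A' preferred over occupancy
  og <- s$atoms[s$atoms$atom_name == "OG", ]
  expect_equal(og$altloc, "B")          # else highest occupancy wins
})

test_that("multi-model files keep only the first model", {
  s <- parse_structure(c(
    "MODEL        1",
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(1, "CA", "ALA", "A", 1, 5, 5, 5),
    "ENDMDL"
  ))
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 0)
})

test_that("chain sequences translate modified residues and map invertibly", {
  s <- pdb_from_lines(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "SEP", "A", 2, 4, 0, 0),
    atom_line(3, "CA", "GLY", "A", 3, 8, 0, 0)
  )
  cs <- chain_sequence(s, "A")
  expect_equal(cs$sequence, "ASG")
  expect_equal(cs$map$seq_num, 1:3)
  # invertible both ways
  expect_equal(cs$map$pos[match(2L, cs$map$seq_num)], 2L)
  expect_equal(cs$map$seq_num[cs$map$pos], 1:3)
  expect_error(chain_sequence(s, "Z"), "no amino-acid")
})

test_that("min_heavy_distance: closed forms, symmetry, brute-force oracle", {
  a <- data.frame(atom_name = "CA", element = "C", x = 0, y = 0, z = 0)
  b <- data.frame(atom_name = "CA", element = "C", x = 3, y = 4, z = 0)
  expect_equal(min_heavy_distance(a, b), 5)
  expect_equal(min_heavy_distance(a, a), 0)
  expect_equal(min_heavy_distance(a, b), min_heavy_distance(b, a))
  h <- data.frame(atom_name = "H", element = "H", x = 0.1, y = 0, z = 0)
  expect_error(min_heavy_distance(h, b), "no heavy atoms")

  set.seed(11)
  m1 <- data.frame(atom_name = "C", element = "C",
                   x = runif(100, 0, 20), y = runif(100, 0, 20),
                   z = runif(100, 0, 20))
  m2 <- data.frame(atom_name = "C", element = "C",
                   x = runif(100, 0, 20), y = runif(100, 0, 20),
                   z = runif(100, 0, 20))
  brute <- min(apply(m1, 1, function(p) {
    sqrt(min((as.numeric(p["x"]) - m2$x)^2 + (as.numeric(p["y"]) - m2$y)^2 +
               (as.numeric(p["z"]) - m2$z)^2))
  }))
  expect_equal(min_heavy_distance(m1, m2), brute, tolerance = 1e-6)
})

test_that("write/parse round trip preserves identifiers and coordinates", {
  for (txt in list(build_helix(n = 10), build_sheet_pair(n = 6),
                   build_ligand_complex(6.4))) {
    s1 <- parse_structure(txt)
    s2 <- parse_structure(write_structure(s1))
    cols <- c("record", "atom_name", "res_name", "chain_id", "seq_num",
              "icode", "element", "is_hetero")
    expect_equal(s2$atoms[, cols], s1$atoms[, cols])
    expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
                 as.matrix(s1$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3)
    expect_equal(s2$resolution, s1$resolution)
  }
})

test_that("parsed fixture coordinates agree with an independent PDB reader", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(sub("\n$", "", build_helix(n = 10)), f)
  ours <- parse_structure(readLines(f))
  ref <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(nrow(ours$atoms), nrow(ref$atom))
  expect_equal(ours$atoms$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(ours$atoms$y, ref$atom$y, tolerance = 1e-6)
  expect_equal(ours$atoms$z, ref$atom$z, tolerance = 1e-6)
  expect_equal(ours$atoms$res_name, ref$atom$resid)
  expect_equal(ours$atoms$seq_num, ref$atom$resno)
})
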