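# Ligand extraction and strong/weak/none drug-association classification.

bundle_site <- function(txt, s, pos = 6L, ptm = "phosphorylation") {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(sub("\n$", "", build_ptm_table(txt, "A", pos, ptm,
                                            window_half = 4)), f)
  map_sites_batch(read_ptm_sites(f), s)
}

test_that("ligand extraction skips waters and blocklisted additives", {
  s <- pdb_from_lines(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "O", "HOH", "A", 100, 5, 0, 0, het = TRUE),
    atom_line(3, "PA", "ATP", "A", 200, 8, 0, 0, element = "P", het = TRUE),
    atom_line(4, "S", "SO4", "A", 300, 12, 0, 0, het = TRUE)
  )
  lig <- extract_ligands(s)
  expect_equal(length(lig), 1L)
  expect_equal(lig[[1]]$het_code, "ATP")
  ann <- data.frame(het_code = "ATP", drug_name = "adenosine triphosphate")
  expect_equal(extract_ligands(s, ann)[[1]]$drug_name,
               "adenosine triphosphate")
  none <- pdb_from_lines(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0))
  expect_equal(length(extract_ligands(none)), 0L)
})

test_that("ligand contact residues respect the inclusive cutoff boundary", {
  s <- pdb_from_lines(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "ALA", "A", 2, 0, 3.9, 0),
    atom_line(3, "CA", "ALA", "A", 3, 0, -4.1, 0),
    atom_line(4, "C1", "LIG", "A", 900, 0, 0, 0, het = TRUE)
  )
  lig <- extract_ligands(s)[[1]]
  cr <- ligand_contact_residues(s, lig, cutoff = 4.0)
  expect_true(1L %in% cr$seq_num)
  expect_true(2L %in% cr$seq_num)    # 3.9 inside
  expect_false(3L %in% cr$seq_num)   # 4.1 outside
  # equals the brute-force scan
  cr_b <- ligand_contact_residues(s, lig, cutoff = 4.0, method = "brute")
  expect_equal(cr, cr_b)
})

test_that("side-chain distances 3.5/6.4/12.1 give strong/weak/none", {
  expected <- c("3.5" = "strong", "6.4" = "weak", "12.1" = "none")
  for (d in names(expected)) {
    txt <- build_ligand_complex(as.numeric(d))
    s <- parse_structure(txt)
    m <- bundle_site(txt, s)
    lg <- extract_ligands(s)[[1]]
    cl <- classify_site_drug(m[1, ], s, lg)
    expect_equal(cl$association, unname(expected[d]))
    expect_equal(cl$sidechain_min_distance, as.numeric(d), tolerance = 0.02)
  }
  # the 12 A rule is inclusive
  txt12 <- build_ligand_complex(12.0)
  s12 <- parse_structure(txt12)
  m12 <- bundle_site(txt12, s12)
  cl12 <- classify_site_drug(m12[1, ], s12, extract_ligands(s12)[[1]])
  expect_equal(cl12$association, "weak")
})

test_that("classifications are monotone under cutoff enlargement", {
  txt <- build_ligand_complex(12.1)
  s <- parse_structure(txt)
  m <- bundle_site(txt, s)
  lg <- extract_ligands(s)[[1]]
  expect_equal(classify_site_drug(m[1, ], s, lg, weak_cutoff = 12)$association,
               "none")
  expect_equal(classify_site_drug(m[1, ], s, lg,
                                  weak_cutoff = 12.2)$association, "weak")
  # widening the contact cutoff promotes weak to strong, never demotes
  txt2 <- build_ligand_complex(6.4)
  s2 <- parse_structure(txt2)
  m2 <- bundle_site(txt2, s2)
  lg2 <- extract_ligands(s2)[[1]]
  expect_equal(classify_site_drug(m2[1, ], s2, lg2)$association, "weak")
  expect_equal(classify_site_drug(m2[1, ], s2, lg2,
                                  contact_cutoff = 7)$association, "strong")
})

test_that("classification is invariant to rigid motion and atom order", {
  txt <- build_ligand_complex(6.4)
  s <- parse_structure(txt)
  m <- bundle_site(txt, s)
  lg <- extract_ligands(s)[[1]]
  base <- classify_site_drug(m[1, ], s, lg)
  sr <- rigid_transform(s)
  clr <- classify_site_drug(m[1, ], sr, extract_ligands(sr)[[1]])
  expect_equal(clr$association, base$association)
  expect_equal(clr$sidechain_min_distance, base$sidechain_min_distance,
               tolerance = 1e-9)
  set.seed(3)
  sp <- s
  sp$atoms <- sp$atoms[sample(nrow(sp$atoms)), ]
  clp <- classify_site_drug(m[1, ], sp, extract_ligands(sp)[[1]])
  expect_equal(clp$association, base$association)
})

test_that("the per-type report tallies strong and weak sites consistently", {
  txt <- build_ligand_complex(3.5, n = 14, site_pos = 7)
  s <- parse_structure(txt)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("\n$", "", build_ptm_table(txt, "A", c(7L, 10L),
                                            c("phosphorylation",
                                              "acetylation"),
                                            window_half = 4)), f)
  m <- map_sites_batch(read_ptm_sites(f), s)
  rep <- site_drug_report(m, s)
  expect_equal(nrow(rep$per_site), 2L)
  for (t in rep$summary$ptm_type) {
    expect_equal(rep$summary$n_on_contact_site[rep$summary$ptm_type == t],
                 sum(rep$per_site$ptm_type == t &
                       rep$per_site$association == "strong"))
    expect_equal(rep$summary$n_within_12A[rep$summary$ptm_type == t],
                 sum(rep$per_site$ptm_type == t &
                       rep$per_site$association == "weak"))
  }
  # no ligands: everything none, zero counts
  prot <- s
  prot$atoms <- prot$atoms[!prot$atoms$is_hetero, ]
  rep0 <- site_drug_report(m, prot)
  expect_true(all(rep0$per_site$association == "none"))
  expect_true(all(rep0$summary$n_on_contact_site == 0L))
})
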