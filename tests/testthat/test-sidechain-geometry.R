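# Orientation angles of side chains relative to the PTM target atom.

test_that("vector angles match closed forms and are clamped and symmetric", {
  expect_equal(vector_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vector_angle(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_equal(vector_angle(c(1, 0, 0), c(3, 0, 0)), 0)
  expect_equal(vector_angle(c(1, 0, 0), c(-2, 0, 0)), 180)
  expect_equal(vector_angle(c(1, 2, 3), c(2, 4, 6)), 0)  # clamped arccos
  expect_error(vector_angle(c(0, 0, 0), c(1, 0, 0)), "zero-length")
  set.seed(5)
  for (k in 1:20) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    expect_equal(vector_angle(u, v), vector_angle(v, u))
    expect_equal(vector_angle(u, v), vector_angle(3.7 * u, 0.2 * v))
  }
})

test_that("theta agrees with the atan2 oracle on random vector pairs", {
  set.seed(42)
  for (k in 1:1000) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    oracle <- atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
    expect_lt(abs(vector_angle(u, v) - oracle), 1e-9)
  }
})

# Geometry with an exactly controlled theta: site SER with OG at distance 5
# along a chosen direction from the neighbor CA; the neighbor side chain (OG)
# points along +x.
theta_structure <- function(theta_deg) {
  a <- theta_deg * pi / 180
  target <- 5 * c(cos(a), sin(a), 0)
  pdb_from_lines(
    atom_line(1, "CA", "SER", "A", 1, target[1] - 1.4, target[2], target[3]),
    atom_line(2, "OG", "SER", "A", 1, target[1], target[2], target[3]),
    atom_line(3, "CA", "SER", "A", 2, 0, 0, 0),
    atom_line(4, "OG", "SER", "A", 2, 1.4, 0, 0)
  )
}

test_that("the functional verdict flips exactly at the cutoff (strict less-than)", {
  site <- fake_mapped_site(seq_num = 1L)
  # realized angles carry PDB 0.001-A coordinate rounding; the verdict must
  # always agree with the realized angle under the strict rule
  for (want in c(45, 79.99, 80, 80.01, 135)) {
    r <- orientation(site, theta_structure(want), "A", 2L)
    expect_equal(r$theta, want, tolerance = 1e-4)
    expect_identical(r$is_functional, r$theta < 80)
  }
  # exactly representable geometry: 45 and 90 degrees are exact in the file,
  # so the strict boundary can be probed with the cutoff itself
  r45 <- orientation(site, theta_structure(45), "A", 2L, theta_cutoff = 45)
  expect_equal(r45$theta, 45, tolerance = 1e-9)
  expect_false(r45$is_functional)     # 45 < 45 is false: strict
  r45b <- orientation(site, theta_structure(45), "A", 2L,
                      theta_cutoff = 45 + 1e-9)
  expect_true(r45b$is_functional)
  r90 <- orientation(site, theta_structure(90), "A", 2L, theta_cutoff = 90)
  expect_equal(r90$theta, 90, tolerance = 1e-9)
  expect_false(r90$is_functional)
  r180 <- orientation(site, theta_structure(180), "A", 2L)
  expect_equal(r180$theta, 180, tolerance = 1e-9)
  expect_false(r180$is_functional)
})

test_that("glycine neighbors carry no angle and are never functional", {
  s <- pdb_from_lines(
    atom_line(1, "CA", "SER", "A", 1, 3.6, 0, 0),
    atom_line(2, "OG", "SER", "A", 1, 5, 0, 0),
    atom_line(3, "CA", "GLY", "A", 2, 0, 0, 0)
  )
  site <- fake_mapped_site(seq_num = 1L)
  r <- orientation(site, s, "A", 2L)
  expect_true(is.na(r$theta))
  expect_false(r$is_functional)
})

test_that("theta is invariant under rigid transforms of the structure", {
  s <- theta_structure(63)
  site <- fake_mapped_site(seq_num = 1L)
  r1 <- orientation(site, s, "A", 2L)
  r2 <- orientation(site, rigid_transform(s), "A", 2L)
  expect_equal(r2$theta, r1$theta, tolerance = 1e-9)
  expect_equal(r2$distance, r1$distance, tolerance = 1e-9)
})

test_that("functional_neighbors returns distance-sorted records within radius", {
  s <- parse_structure(build_helix(n = 20))
  hx <- build_helix(n = 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("\n$", "", build_ptm_table(hx, "A", 15L, "phosphorylation",
                                            window_half = 5)), f)
  m <- map_sites_batch(read_ptm_sites(f), s)
  fn <- functional_neighbors(m[1, ], s, radius = 12)
  expect_gt(nrow(fn), 0L)
  expect_true(all(diff(fn$distance) >= 0))
  expect_true(all(fn$distance <= 12))
  # the substrate residue itself is excluded
  expect_false(any(fn$seq_num == m$seq_num[1]))
  # verdicts agree with their own angles
  has_theta <- !is.na(fn$theta)
  expect_equal(fn$is_functional[has_theta], fn$theta[has_theta] < 80)
  # shrinking the radius to exclude everything empties the result
  fn0 <- functional_neighbors(m[1, ], s, radius = 0.5)
  expect_equal(nrow(fn0), 0L)
})

test_that("atom tables cover the supported types and accept overrides", {
  fa <- functional_atom_table()
  expect_equal(length(fa), 20L)
  expect_true(is.na(fa[["G"]]))
  expect_equal(fa[["S"]], "OG")
  fa2 <- functional_atom_table(overrides = c(H = "ND1"))
  expect_equal(fa2[["H"]], "ND1")
  ta <- target_atom_table()
  expect_equal(ta$atom[ta$ptm_type == "n-linked glycosylation" &
                         ta$residue == "N"], "ND2")
  expect_equal(ta$atom[ta$ptm_type == "phosphorylation" & ta$residue == "S"],
               "OG")
  expect_false(any(duplicated(paste(ta$ptm_type, ta$residue))))
  ta2 <- target_atom_table(overrides = c("phosphorylation|S" = "CB"))
  expect_equal(ta2$atom[ta2$ptm_type == "phosphorylation" &
                          ta2$residue == "S"], "CB")
})
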