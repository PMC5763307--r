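# Typed residue contacts and the more-than-five-pairs interface rule.

test_that("each typed contact criterion fires at its printed cutoff", {
  sb <- parse_structure(build_interface(data.frame(kind = "salt_bridge",
                                                   distance = 5.4)))
  c1 <- detect_contacts(sb, domain_range("A", 1, 1), domain_range("B", 1, 1))
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$kind, "salt_bridge")
  expect_equal(c1$distance, 5.4, tolerance = 0.02)

  hb <- parse_structure(build_interface(data.frame(kind = "hbond",
                                                   distance = 3.4)))
  c2 <- detect_contacts(hb, domain_range("A", 1, 1), domain_range("B", 1, 1))
  expect_equal(c2$kind, "hbond")

  far <- parse_structure(build_interface(data.frame(kind = "vdw",
                                                    distance = 5.2)))
  c3 <- detect_contacts(far, domain_range("A", 1, 1), domain_range("B", 1, 1))
  expect_equal(nrow(c3), 0L)   # C-C 5.2 A exceeds the 5.0 A rule

  near <- parse_structure(build_interface(data.frame(kind = "vdw",
                                                     distance = 4.8)))
  c4 <- detect_contacts(near, domain_range("A", 1, 1), domain_range("B", 1, 1))
  expect_equal(c4$kind, "vdw")
})

test_that("six contacting pairs form an interaction, five do not", {
  s6 <- parse_structure(build_interface(data.frame(kind = rep("vdw", 6),
                                                   distance = 4.8)))
  r6 <- detect_interface(s6, domain_range("A", 1, 6), domain_range("B", 1, 6))
  expect_equal(r6$n_pairs, 6L)
  expect_true(r6$is_interaction)

  s5 <- parse_structure(build_interface(data.frame(kind = rep("vdw", 5),
                                                   distance = 4.8)))
  r5 <- detect_interface(s5, domain_range("A", 1, 5), domain_range("B", 1, 5))
  expect_equal(r5$n_pairs, 5L)
  expect_false(r5$is_interaction)

  # zero pairs: empty contact set
  s0 <- parse_structure(build_interface(data.frame(kind = "vdw",
                                                   distance = 20)))
  r0 <- detect_interface(s0, domain_range("A", 1, 1), domain_range("B", 1, 1))
  expect_false(r0$is_interaction)
  expect_equal(nrow(r0$contact_residues), 0L)
})

test_that("contact detection is symmetric and unaffected by distant atoms", {
  txt <- build_interface(data.frame(kind = c("vdw", "salt_bridge", "hbond"),
                                    distance = c(4.8, 5.4, 3.4)))
  s <- parse_structure(txt)
  da <- domain_range("A", 1, 3); db <- domain_range("B", 1, 3)
  ab <- detect_contacts(s, da, db)
  ba <- detect_contacts(s, db, da)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$seq_a, ba$seq_b)
  expect_equal(sort(ab$kind), sort(ba$kind))
  expect_equal(sort(ab$distance), sort(ba$distance), tolerance = 1e-9)

  # an extra atom farther than 5.5 A from everything changes nothing
  s2 <- s
  extra <- s$atoms[1, , drop = FALSE]
  extra$x <- extra$x + 500
  extra$atom_name <- "CB"; extra$element <- "C"
  s2$atoms <- rbind(s2$atoms, extra)
  expect_equal(detect_contacts(s2, da, db)[, c("seq_a", "seq_b", "kind")],
               ab[, c("seq_a", "seq_b", "kind")])
})

test_that("grid and brute contact searches agree on random two-chain fixtures", {
  for (seed in 1:8) {
    s <- random_two_chain(seed, n = 15L)
    da <- domain_range("A", 1, 15); db <- domain_range("B", 1, 15)
    g <- detect_contacts(s, da, db, method = "grid")
    b <- detect_contacts(s, da, db, method = "brute")
    expect_equal(g, b)
  }
})

test_that("same-chain domain pairs are rejected", {
  s <- parse_structure(build_interface(data.frame(kind = "vdw",
                                                  distance = 4.8)))
  expect_error(detect_contacts(s, domain_range("A", 1, 1),
                               domain_range("A", 1, 1)),
               "different chains")
})

test_that("domain pair enumeration crosses chains only", {
  doms <- rbind(domain_range("A", 1, 50, "d1"), domain_range("A", 60, 90, "d2"),
                domain_range("B", 1, 40, "d3"))
  prs <- enumerate_domain_pairs(doms)
  expect_equal(nrow(prs), 2L)
  expect_true(all(doms$chain_id[prs$a] != doms$chain_id[prs$b]))

  same <- rbind(domain_range("A", 1, 10, "d1"), domain_range("A", 20, 30, "d2"))
  expect_equal(nrow(enumerate_domain_pairs(same)), 0L)

  # combinatorial oracle on a random chain assignment
  set.seed(9)
  chains <- sample(c("A", "B", "C"), 8, replace = TRUE)
  doms2 <- do.call(rbind, lapply(seq_along(chains), function(i) {
    domain_range(chains[i], 1 + 10 * i, 5 + 10 * i, paste0("d", i))
  }))
  want <- sum(outer(chains, chains, "!=")[upper.tri(diag(8))])
  expect_equal(nrow(enumerate_domain_pairs(doms2)), want)
})

test_that("sites are on an interface only by strict contact-set membership", {
  s6 <- parse_structure(build_interface(data.frame(kind = rep("vdw", 6),
                                                   distance = 4.8)))
  r6 <- detect_interface(s6, domain_range("A", 1, 6), domain_range("B", 1, 6))
  on <- fake_mapped_site(chain_id = "A", seq_num = 3L, residue = "A",
                         ptm_type = "acetylation")
  v <- classify_site_ppi(on, list(r6))
  expect_true(v$on_interface)
  expect_equal(v$interfaces, 1L)

  # adjacent residue that is not itself contacting: rebuild with a gap pair
  s5 <- parse_structure(build_interface(data.frame(
    kind = rep("vdw", 6), distance = c(4.8, 4.8, 20, 4.8, 4.8, 4.8))))
  r5 <- detect_interface(s5, domain_range("A", 1, 6), domain_range("B", 1, 6))
  off <- fake_mapped_site(chain_id = "A", seq_num = 3L, residue = "A",
                          ptm_type = "acetylation")
  expect_false(classify_site_ppi(off, list(r5))$on_interface)
  expect_false(classify_site_ppi(on, list())$on_interface)
})
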