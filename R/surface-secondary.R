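# Solvent-accessible surface area (Shrake-Rupley sphere sampling with a
# deterministic golden-section spiral point set) and a reduced three-state
# secondary-structure assignment based on Kabsch-Sander backbone hydrogen-bond
# energies.

# Orthonormal frame derived from the atom cloud itself (centroid-to-extreme
# directions), so it co-rotates with the molecule. Falls back to the identity
# for degenerate (single-atom or collinear) clouds.
#' @keywords internal
intrinsic_frame <- function(xyz) {
  if (nrow(xyz) < 3L) return(diag(3))
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2L, ctr)
  d <- sqrt(rowSums(rel^2))
  v1 <- rel[which.max(d), ]
  n1 <- sqrt(sum(v1^2))
  if (n1 < 1e-8) return(diag(3))
  v1 <- v1 / n1
  # second axis: atom with the largest component perpendicular to v1
  perp <- rel - outer(as.vector(rel %*% v1), v1)
  pn <- sqrt(rowSums(perp^2))
  if (max(pn) < 1e-6) return(diag(3))
  v2 <- perp[which.max(pn), ] / max(pn)
  v3 <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
          v1[3L] * v2[1L] - v1[1L] * v2[3L],
          v1[1L] * v2[2L] - v1[2L] * v2[1L])
  cbind(v1, v2, v3)
}

# Deterministic, approximately uniform points on the unit sphere.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA is the fraction of `n_points` test points on the solvent-
#' expanded sphere (radius r_vdw + probe) not buried inside any other atom's
#' expanded sphere, times the sphere area. Heavy atoms only; waters always
#' excluded; hetero atoms (ligands) excluded from the surface by default.
#'
#' @param s a `ptm_structure`.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960, minimum 100).
#' @param include_hetero include non-water HETATM records in the calculation.
#' @param chain_id optional chain filter: compute on that chain in isolation.
#' @return list of class `sasa_result`: `atoms` (atom table with `sasa`
#'   column), `residues` (chain_id, seq_num, icode, res_name, aa, sasa,
#'   rel_acc), `total`.
#' @export
#' @examples
#' res <- calc_sasa(parse_structure(build_helix(n = 8)))
#' head(res$residues)
calc_sasa <- function(s, probe = 1.4, n_points = 960L,
                      include_hetero = FALSE, chain_id = NULL) {
  stopifnot(inherits(s, "ptm_structure"), probe > 0, n_points >= 100L)
  a <- heavy_atoms(s$atoms)
  a <- a[!(a$res_name %in% WATER_CODES), , drop = FALSE]
  if (!include_hetero) a <- a[!a$is_hetero | protein_mask(a), , drop = FALSE]
  if (!is.null(chain_id)) a <- a[a$chain_id %in% chain_id, , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy atoms selected for SASA")
  unknown <- setdiff(unique(a$element), names(VDW_RADII))
  if (length(unknown) > 0L) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  r <- VDW_RADII[a$element] + probe
  xyz <- atom_xyz(a)
  # Orient the quadrature sphere in a molecule-intrinsic frame so that the
  # computed areas are invariant under rigid motion of the structure.
  pts <- sphere_points(n_points) %*% t(intrinsic_frame(xyz))
  n <- nrow(a)
  # Candidate occluders: pairs closer than the sum of expanded radii.
  maxr <- max(r)
  cand <- neighbor_pairs(xyz, xyz, 2 * maxr, method = "grid")
  cand <- cand[cand$i != cand$j & cand$dist < r[cand$i] + r[cand$j], ,
               drop = FALSE]
  nb <- split(cand$j, factor(cand$i, levels = seq_len(n)))
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * r[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb[[i]]) {
      d2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      exposed <- exposed & d2 > r[j]^2
      if (!any(exposed)) break
    }
    sasa[i] <- sum(exposed) / n_points * 4 * pi * r[i]^2
  }
  a$sasa <- sasa
  key <- paste(a$chain_id, a$seq_num, a$icode, sep = "\r")
  first <- !duplicated(key)
  res <- a[first, c("chain_id", "seq_num", "icode", "res_name")]
  res$aa <- aa_one_letter(res$res_name)
  res$sasa <- as.vector(tapply(a$sasa, factor(key, levels = key[first]), sum))
  res$rel_acc <- res$sasa / MAX_ACC_GXG[res$aa]
  rownames(res) <- NULL
  structure(list(atoms = a, residues = res, total = sum(sasa)),
            class = "sasa_result")
}

# ---- secondary structure -----------------------------------------------------

# Backbone amide H reconstructed on the bisector of (N - C_prev) and (N - CA),
# 1.0 A from N; prolines and chain-start residues have no donor H.
#' @keywords internal
backbone_table <- function(s) {
  a <- heavy_atoms(s$atoms)
  a <- a[protein_mask(a), , drop = FALSE]
  rt <- residue_table(s)
  if (nrow(rt) == 0L) stop("no protein residues for secondary structure")
  pick <- function(name) {
    sel <- a[a$atom_name == name, , drop = FALSE]
    idx <- match(paste(rt$chain_id, rt$seq_num, rt$icode, sep = "\r"),
                 paste(sel$chain_id, sel$seq_num, sel$icode, sep = "\r"))
    cbind(sel$x[idx], sel$y[idx], sel$z[idx])
  }
  list(rt = rt, N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"))
}

#' Three-state secondary structure (H/E/C)
#'
#' Backbone hydrogen bonds are detected with the Kabsch-Sander electrostatic
#' energy E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) kcal/mol
#' (amide H reconstructed from backbone geometry), bonded when E < -0.5.
#' Two consecutive i -> i+4 turns assign helix (H) to the four spanned
#' residues; Kabsch-Sander parallel/antiparallel bridge patterns assign strand
#' (E), including across chains; everything else is coil (C). Residues with
#' missing backbone atoms are C and flagged.
#'
#' @param s a `ptm_structure`.
#' @param chain_id optional chain filter on the *report* (hydrogen bonding is
#'   always evaluated on the full structure so that inter-chain sheets pair).
#' @param energy_cutoff H-bond energy threshold in kcal/mol (default -0.5).
#' @return data.frame: chain_id, seq_num, icode, res_name, aa, ss
#'   (`"H"`, `"E"` or `"C"`), incomplete_backbone.
#' @export
secondary_structure <- function(s, chain_id = NULL, energy_cutoff = -0.5) {
  bb <- backbone_table(s)
  rt <- bb$rt
  n <- nrow(rt)
  complete <- !is.na(bb$N[, 1L]) & !is.na(bb$CA[, 1L]) &
    !is.na(bb$C[, 1L]) & !is.na(bb$O[, 1L])
  # connected(i): residue i follows i-1 in the same chain with contiguous
  # author numbering (an insertion-coded successor also counts).
  connected <- c(FALSE, rt$chain_id[-1L] == rt$chain_id[-n] &
                   (rt$seq_num[-1L] - rt$seq_num[-n] == 1L |
                      (rt$seq_num[-1L] == rt$seq_num[-n] &
                         rt$icode[-1L] != rt$icode[-n])))
  H <- matrix(NA_real_, n, 3L)
  for (i in which(connected & complete)) {
    if (!complete[i - 1L]) next
    if (toupper(rt$res_name[i]) == "PRO") next
    u1 <- bb$N[i, ] - bb$C[i - 1L, ]
    u2 <- bb$N[i, ] - bb$CA[i, ]
    u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
    u <- u1 + u2
    H[i, ] <- bb$N[i, ] + u / sqrt(sum(u^2))
  }
  # hb[i, j]: C=O of residue i accepts the amide H-N of residue j.
  donors <- which(!is.na(H[, 1L]))
  acceptors <- which(complete)
  hb <- matrix(FALSE, n, n)
  if (length(donors) > 0L && length(acceptors) > 0L) {
    # restrict to donor/acceptor pairs with N within 7 A of O
    cand <- neighbor_pairs(bb$O[acceptors, , drop = FALSE],
                           bb$N[donors, , drop = FALSE], 7.0, method = "grid")
    for (k in seq_len(nrow(cand))) {
      i <- acceptors[cand$i[k]]  # acceptor (C=O)
      j <- donors[cand$j[k]]     # donor (N-H)
      if (i == j) next
      d_on <- sqrt(sum((bb$O[i, ] - bb$N[j, ])^2))
      d_ch <- sqrt(sum((bb$C[i, ] - H[j, ])^2))
      d_oh <- sqrt(sum((bb$O[i, ] - H[j, ])^2))
      d_cn <- sqrt(sum((bb$C[i, ] - bb$N[j, ])^2))
      if (min(d_on, d_ch, d_oh, d_cn) < 0.5) next  # clashing geometry
      e <- 0.084 * 332 * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
      if (e < energy_cutoff) hb[i, j] <- TRUE
    }
  }
  run_ok <- function(i, k) {
    # residues i..i+k all pairwise connected in sequence
    if (i < 1L || i + k > n) return(FALSE)
    all(connected[seq.int(i + 1L, i + k)])
  }
  # 4-turn at i: CO(i) accepts NH(i+4)
  turn4 <- vapply(seq_len(n), function(i) {
    run_ok(i, 4L) && hb[i, i + 4L]
  }, logical(1L))
  ss <- rep("C", n)
  for (i in which(turn4)) {
    if (i > 1L && turn4[i - 1L]) ss[i:(i + 3L)] <- "H"
  }
  hbond <- function(i, j) !is.na(i) && !is.na(j) && i >= 1L && j >= 1L &&
    i <= n && j <= n && hb[i, j]
  prv <- function(i) if (i > 1L && connected[i]) i - 1L else NA_integer_
  nxt <- function(i) if (i < n && connected[i + 1L]) i + 1L else NA_integer_
  bridge <- matrix(FALSE, n, n)
  # candidate bridge partners: C-alpha within 6.5 A (covers beta ladders)
  seen <- matrix(integer(0), ncol = 2L)
  okca <- which(!is.na(bb$CA[, 1L]))
  if (length(okca) > 1L) {
    cp <- neighbor_pairs(bb$CA[okca, , drop = FALSE],
                         bb$CA[okca, , drop = FALSE], 6.5, method = "grid")
    cp <- cp[okca[cp$i] < okca[cp$j], , drop = FALSE]
    seen <- cbind(okca[cp$i], okca[cp$j])
  }
  for (r in seq_len(nrow(seen))) {
    i <- seen[r, 1L]; j <- seen[r, 2L]
    if (rt$chain_id[i] == rt$chain_id[j] && abs(i - j) < 3L) next
    par <- (hbond(prv(i), j) && hbond(j, nxt(i))) ||
      (hbond(prv(j), i) && hbond(i, nxt(j)))
    anti <- (hbond(i, j) && hbond(j, i)) ||
      (hbond(prv(i), nxt(j)) && hbond(prv(j), nxt(i)))
    if (par || anti) bridge[i, j] <- bridge[j, i] <- TRUE
  }
  in_bridge <- rowSums(bridge) > 0
  ss[in_bridge & ss != "H"] <- "E"
  ss[!complete] <- "C"
  out <- rt[, c("chain_id", "seq_num", "icode", "res_name", "aa")]
  out$ss <- ss
  out$incomplete_backbone <- !complete
  if (!is.null(chain_id)) out <- out[out$chain_id %in% chain_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site surface and secondary-structure summary
#'
#' Joins the SASA and secondary-structure computations for one mapped site:
#' its three-state status, residue SASA and relative accessibility (computed
#' on the full complex and on the isolated chain), and the states of up to
#' three flanking residues on each side.
#'
#' @param site uniquely mapped site row.
#' @param s a `ptm_structure`.
#' @param probe,n_points passed to [calc_sasa()].
#' @return one-row data.frame: ss, sasa_complex, rel_acc_complex, sasa_chain,
#'   rel_acc_chain, flank_ss (string of at most 7 states, site at center
#'   marked by its own state).
#' @export
site_surface_summary <- function(site, s, probe = 1.4, n_points = 960L) {
  site <- assert_unique_mapping(site)
  ssall <- secondary_structure(s)
  idx <- which(ssall$chain_id == site$chain_id &
                 ssall$seq_num == site$seq_num & ssall$icode == site$icode)
  if (length(idx) != 1L) stop("mapped residue not found in structure")
  chain_rows <- which(ssall$chain_id == site$chain_id)
  lo <- max(min(chain_rows), idx - 3L)
  hi <- min(max(chain_rows), idx + 3L)
  flank <- paste(ssall$ss[lo:hi], collapse = "")
  sc <- calc_sasa(s, probe = probe, n_points = n_points)
  si <- calc_sasa(s, probe = probe, n_points = n_points,
                  chain_id = site$chain_id)
  pick <- function(res) {
    k <- which(res$chain_id == site$chain_id & res$seq_num == site$seq_num &
                 res$icode == site$icode)
    if (length(k) != 1L) c(NA_real_, NA_real_) else
      c(res$sasa[k], res$rel_acc[k])
  }
  pc <- pick(sc$residues)
  pi_ <- pick(si$residues)
  data.frame(
    chain_id = site$chain_id, seq_num = site$seq_num, icode = site$icode,
    ss = ssall$ss[idx], sasa_complex = pc[1L], rel_acc_complex = pc[2L],
    sasa_chain = pi_[1L], rel_acc_chain = pi_[2L], flank_ss = flank,
    stringsAsFactors = FALSE
  )
}
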