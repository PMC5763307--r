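# Spatial amino-acid composition around a mapped PTM site: cumulative counts
# and relative frequencies of the 20 amino acids within 2-12 A radii, and the
# acid/base division of the neighborhood.

#' Radial amino-acid composition around a mapped site
#'
#' For each radius r, counts the residues whose C-alpha lies within r of the
#' site's reference point (its PTM target atom when resolved, else C-alpha;
#' or C-alpha with `reference = "ca"`). Counting is cumulative (spheres, not
#' shells); the substrate residue itself is excluded; waters and non-protein
#' heteros never count.
#'
#' @param site uniquely mapped site row.
#' @param s a `ptm_structure`.
#' @param radii numeric vector of radii in Angstrom (default 2:12).
#' @param reference `"target"` (default) or `"ca"`: reference point on the
#'   substrate residue.
#' @param target_atoms table from [target_atom_table()].
#' @return list of class `radial_composition`: `radii`, `counts` (radius x 20
#'   amino-acid integer matrix, cumulative), `freqs` (same shape, rows sum to 1
#'   where the total is positive), `total` (neighbors per radius).
#' @export
radial_composition <- function(site, s, radii = 2:12,
                               reference = c("target", "ca"),
                               target_atoms = target_atom_table()) {
  site <- assert_unique_mapping(site)
  reference <- match.arg(reference)
  stopifnot(length(radii) > 0L, all(radii > 0))
  radii <- sort(as.numeric(radii))
  ref <- site_reference_point(site, s, reference, target_atoms)
  nb <- neighbor_ca_table(site, s)
  aa_levels <- unname(AA_3TO1)
  counts <- matrix(0L, nrow = length(radii), ncol = length(aa_levels),
                   dimnames = list(as.character(radii), aa_levels))
  if (nrow(nb) > 0L) {
    d <- as.vector(cross_distances(atom_xyz(nb), matrix(ref, nrow = 1L)))
    for (i in seq_along(radii)) {
      sel <- nb$aa[d <= radii[i]]
      sel <- sel[sel %in% aa_levels]
      if (length(sel) > 0L) {
        tb <- table(factor(sel, levels = aa_levels))
        counts[i, ] <- as.integer(tb)
      }
    }
  }
  total <- rowSums(counts)
  freqs <- counts / ifelse(total > 0, total, 1)
  structure(list(radii = radii, counts = counts, freqs = freqs,
                 total = total),
            class = "radial_composition")
}

#' @keywords internal
site_reference_point <- function(site, s, reference, target_atoms) {
  if (reference == "target") {
    t <- site_target_atom(site, s, target_atoms)
    return(c(t$x, t$y, t$z))
  }
  at <- residue_atoms(s, site$chain_id, site$seq_num, site$icode)
  ca <- at[at$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("site residue lacks a C-alpha atom")
  c(ca$x[1L], ca$y[1L], ca$z[1L])
}

# C-alpha atoms of all protein residues except the substrate, with one-letter
# codes attached.
#' @keywords internal
neighbor_ca_table <- function(site, s) {
  a <- s$atoms
  cas <- a[protein_mask(a) & a$atom_name == "CA" &
             !(a$element %in% c("H", "D")), , drop = FALSE]
  self <- cas$chain_id == site$chain_id & cas$seq_num == site$seq_num &
    cas$icode == site$icode
  cas <- cas[!self, , drop = FALSE]
  cas$aa <- aa_one_letter(cas$res_name)
  cas
}

#' Acid/base division of a site's spatial neighborhood
#'
#' Classifies each neighbor within `radius` as acidic (D, E), basic (K, R, H)
#' or neutral.
#'
#' @inheritParams radial_composition
#' @param radius single radius in Angstrom.
#' @return one-row data.frame: radius, n_acidic, n_basic, n_neutral, n_total.
#' @export
acid_base_division <- function(site, s, radius = 12,
                               reference = c("target", "ca"),
                               target_atoms = target_atom_table()) {
  site <- assert_unique_mapping(site)
  reference <- match.arg(reference)
  stopifnot(length(radius) == 1L, radius > 0)
  ref <- site_reference_point(site, s, reference, target_atoms)
  nb <- neighbor_ca_table(site, s)
  aa <- character(0)
  if (nrow(nb) > 0L) {
    d <- as.vector(cross_distances(atom_xyz(nb), matrix(ref, nrow = 1L)))
    aa <- nb$aa[d <= radius]
  }
  data.frame(
    radius = radius,
    n_acidic = sum(aa %in% ACIDIC_AA),
    n_basic = sum(aa %in% BASIC_AA),
    n_neutral = sum(!(aa %in% c(ACIDIC_AA, BASIC_AA))),
    n_total = length(aa)
  )
}

#' Long-format table of a radial composition
#'
#' @param rc a `radial_composition`.
#' @return data.frame with columns radius, amino_acid, count, freq.
#' @export
radial_composition_table <- function(rc) {
  stopifnot(inherits(rc, "radial_composition"))
  aa <- colnames(rc$counts)
  out <- expand.grid(amino_acid = aa, radius = rc$radii,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("radius", "amino_acid")]
  out$count <- as.vector(t(rc$counts))
  out$freq <- as.vector(t(rc$freqs))
  out
}

#' Simple radial cumulative propensity plot
#'
#' Line plot of per-amino-acid cumulative frequency against radius (base
#' graphics helper; amino acids absent at the largest radius are dropped).
#'
#' @param rc a `radial_composition`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_radial_profile <- function(rc, ...) {
  stopifnot(inherits(rc, "radial_composition"))
  keep <- rc$counts[nrow(rc$counts), ] > 0
  if (!any(keep)) {
    warning("no neighbors at any radius; nothing to plot")
    return(invisible(NULL))
  }
  graphics::matplot(rc$radii, rc$freqs[, keep, drop = FALSE], type = "b",
                    pch = 1, lty = 1, xlab = "radius (Angstrom)",
                    ylab = "cumulative frequency", ...)
  graphics::legend("topright", legend = colnames(rc$counts)[keep],
                   col = seq_len(sum(keep)), lty = 1, cex = 0.7)
  invisible(rc)
}
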