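# Classification of PTM sites against bound small-molecule ligands: a site in
# the ligand contact set is strongly associated with drug binding; a site
# whose side chain lies within 12 A of the ligand is weakly associated.

#' Extract bound ligands from a structure
#'
#' All HETATM residue groups except waters and a configurable crystallization-
#' additive blocklist. Drug-name annotations (het code to name) are attached
#' when supplied.
#'
#' @param s a `ptm_structure`.
#' @param annotations optional data.frame with columns `het_code`,
#'   `drug_name` (and optionally `drug_id`).
#' @param blocklist het codes to skip (defaults to common additives such as
#'   SO4, GOL, PEG, EDO).
#' @return list of ligand records, each a list with `het_code`, `chain_id`,
#'   `seq_num`, `atoms` (heavy-atom data.frame), `drug_name`.
#' @export
extract_ligands <- function(s, annotations = NULL,
                            blocklist = LIGAND_BLOCKLIST) {
  a <- heavy_atoms(s$atoms)
  a <- a[a$is_hetero & !(a$res_name %in% WATER_CODES) &
           !(a$res_name %in% blocklist) &
           !is_standard_or_modified_aa(a$res_name), , drop = FALSE]
  if (nrow(a) == 0L) return(list())
  key <- paste(a$res_name, a$chain_id, a$seq_num, a$icode, sep = "\r")
  groups <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  lapply(groups, function(rows) {
    at <- a[rows, , drop = FALSE]
    name <- NA_character_
    if (!is.null(annotations) && "het_code" %in% names(annotations)) {
      m <- match(at$res_name[1L], annotations$het_code)
      if (!is.na(m)) name <- annotations$drug_name[m]
    }
    list(het_code = at$res_name[1L], chain_id = at$chain_id[1L],
         seq_num = at$seq_num[1L], atoms = at, drug_name = name)
  })
}

#' Read ligand/drug annotations from TSV
#'
#' Expected header: het_code, drug_name (optionally drug_id).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_ligand_annotations <- function(path) {
  if (!file.exists(path)) stop("ligand annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("het_code", "drug_name") %in% names(df))) {
    stop("ligand annotation table needs columns het_code, drug_name")
  }
  df
}

#' Protein residues in contact with a ligand
#'
#' @param s a `ptm_structure`.
#' @param ligand one ligand record from [extract_ligands()].
#' @param cutoff heavy-atom contact cutoff in Angstrom (default 4.0,
#'   inclusive).
#' @param method neighbor-search method.
#' @return data.frame of contact residues: chain_id, seq_num, icode,
#'   res_name, min_dist.
#' @export
ligand_contact_residues <- function(s, ligand, cutoff = 4.0,
                                    method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(cutoff > 0)
  a <- heavy_atoms(s$atoms)
  a <- a[protein_mask(a), , drop = FALSE]
  out <- data.frame(chain_id = character(0), seq_num = integer(0),
                    icode = character(0), res_name = character(0),
                    min_dist = numeric(0), stringsAsFactors = FALSE)
  if (nrow(a) == 0L) return(out)
  prs <- neighbor_pairs(atom_xyz(a), atom_xyz(ligand$atoms), cutoff,
                        method = method)
  if (nrow(prs) == 0L) return(out)
  key <- paste(a$chain_id[prs$i], a$seq_num[prs$i], a$icode[prs$i], sep = "\r")
  best <- tapply(seq_len(nrow(prs)), factor(key, levels = unique(key)),
                 function(k) k[which.min(prs$dist[k])])
  sel <- prs$i[as.integer(best)]
  out <- data.frame(
    chain_id = a$chain_id[sel], seq_num = a$seq_num[sel],
    icode = a$icode[sel], res_name = a$res_name[sel],
    min_dist = prs$dist[as.integer(best)], stringsAsFactors = FALSE
  )
  out[order(out$chain_id, out$seq_num, out$icode), , drop = FALSE]
}

# Side-chain heavy atoms of a residue (non-backbone); glycine falls back to
# its C-alpha as proxy.
#' @keywords internal
sidechain_atoms <- function(res_atoms) {
  h <- heavy_atoms(res_atoms)
  sc <- h[!(h$atom_name %in% BACKBONE_ATOMS), , drop = FALSE]
  if (nrow(sc) == 0L) sc <- h[h$atom_name == "CA", , drop = FALSE]
  sc
}

#' Classify a mapped site against one ligand
#'
#' Strong association: the site residue belongs to the ligand's contact set
#' (any heavy atom within `contact_cutoff`). Weak association: not strong, but
#' the minimum side-chain-heavy-atom to ligand-heavy-atom distance is within
#' `weak_cutoff`. Otherwise none. Both cutoffs are inclusive.
#'
#' @param site uniquely mapped site row.
#' @param s a `ptm_structure`.
#' @param ligand one ligand record from [extract_ligands()].
#' @param contact_cutoff contact distance in Angstrom (default 4.0).
#' @param weak_cutoff outer side-chain distance in Angstrom (default 12.0).
#' @return one-row data.frame: het_code, drug_name, association (`"strong"`,
#'   `"weak"` or `"none"`), min_distance (any heavy atom),
#'   sidechain_min_distance.
#' @export
classify_site_drug <- function(site, s, ligand, contact_cutoff = 4.0,
                               weak_cutoff = 12.0) {
  site <- assert_unique_mapping(site)
  stopifnot(contact_cutoff > 0, weak_cutoff > 0)
  res <- residue_atoms(s, site$chain_id, site$seq_num, site$icode)
  if (nrow(res) == 0L) stop("mapped residue not found in structure")
  min_all <- min_heavy_distance(res, ligand$atoms)
  sc <- sidechain_atoms(res)
  min_sc <- if (nrow(sc) > 0L) min_heavy_distance(sc, ligand$atoms) else
    min_all
  assoc <- if (min_all <= contact_cutoff) {
    "strong"
  } else if (min_sc <= weak_cutoff) {
    "weak"
  } else {
    "none"
  }
  data.frame(
    het_code = ligand$het_code, drug_name = ligand$drug_name,
    association = assoc, min_distance = min_all,
    sidechain_min_distance = min_sc, stringsAsFactors = FALSE
  )
}

#' Per-PTM-type drug-association report
#'
#' Counts, for each modification type, the sites strongly associated with any
#' ligand (on a drug contact site) and the sites weakly associated (side chain
#' within the outer cutoff of a ligand but not in contact). Each site counts
#' once; strong precludes weak.
#'
#' @param mapped data.frame of mapped sites (only uniquely mapped rows are
#'   classified).
#' @param s a `ptm_structure`.
#' @param annotations optional ligand annotation data.frame.
#' @param contact_cutoff,weak_cutoff cutoffs in Angstrom.
#' @param blocklist passed to [extract_ligands()].
#' @return list: `per_site` (one row per uniquely mapped site with its best
#'   association and nearest ligand) and `summary` (ptm_type,
#'   n_on_contact_site, n_within_12A).
#' @export
site_drug_report <- function(mapped, s, annotations = NULL,
                             contact_cutoff = 4.0, weak_cutoff = 12.0,
                             blocklist = LIGAND_BLOCKLIST) {
  ligands <- extract_ligands(s, annotations, blocklist)
  um <- mapped[mapped$match_kind == "unique", , drop = FALSE]
  per_site <- data.frame(
    protein_id = character(0), position = integer(0), ptm_type = character(0),
    chain_id = character(0), seq_num = integer(0), association = character(0),
    het_code = character(0), min_distance = numeric(0),
    sidechain_min_distance = numeric(0), stringsAsFactors = FALSE
  )
  lvl <- c(strong = 1L, weak = 2L, none = 3L)
  for (i in seq_len(nrow(um))) {
    site <- um[i, , drop = FALSE]
    best <- NULL
    for (lg in ligands) {
      cl <- classify_site_drug(site, s, lg, contact_cutoff, weak_cutoff)
      if (is.null(best) || lvl[[cl$association]] < lvl[[best$association]] ||
          (lvl[[cl$association]] == lvl[[best$association]] &&
             cl$sidechain_min_distance < best$sidechain_min_distance)) {
        best <- cl
      }
    }
    if (is.null(best)) {
      best <- data.frame(het_code = NA_character_, drug_name = NA_character_,
                         association = "none", min_distance = NA_real_,
                         sidechain_min_distance = NA_real_,
                         stringsAsFactors = FALSE)
    }
    per_site <- rbind(per_site, data.frame(
      protein_id = site$protein_id, position = site$position,
      ptm_type = site$ptm_type, chain_id = site$chain_id,
      seq_num = site$seq_num, association = best$association,
      het_code = best$het_code, min_distance = best$min_distance,
      sidechain_min_distance = best$sidechain_min_distance,
      stringsAsFactors = FALSE
    ))
  }
  types <- unique(per_site$ptm_type)
  summary <- data.frame(
    ptm_type = types,
    n_on_contact_site = vapply(types, function(t) {
      sum(per_site$ptm_type == t & per_site$association == "strong")
    }, integer(1L)),
    n_within_12A = vapply(types, function(t) {
      sum(per_site$ptm_type == t & per_site$association == "weak")
    }, integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(per_site = per_site, summary = summary)
}
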