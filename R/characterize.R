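# End-to-end pipeline: map PTM sites onto a structure and emit the per-site
# five-property characterization, interface verdicts and drug associations.

#' Pipeline configuration
#'
#' Collects the input paths and every threshold of the analysis. Defaults:
#' radii 2-12 A, theta cutoff 80 degrees, contact criteria 3.5/5.5/5.0 A,
#' interface threshold of more than 5 residue pairs, drug cutoffs 4.0/12.0 A,
#' resolution cutoff 2.5 A (filter off unless `enforce_resolution`).
#'
#' @param structure path to a PDB file.
#' @param sites path to the PTM-site TSV.
#' @param domains optional path to the domain-range TSV.
#' @param ligands optional path to the ligand-annotation TSV.
#' @param out_dir output directory (created if missing).
#' @param radii composition radii (Angstrom).
#' @param theta_cutoff functional side-chain orientation cutoff (degrees).
#' @param hbond_cutoff,salt_cutoff,vdw_cutoff contact criteria (Angstrom).
#' @param pair_threshold interface requires more than this many residue pairs.
#' @param contact_cutoff,weak_cutoff drug association cutoffs (Angstrom).
#' @param resolution_cutoff resolution filter cutoff (Angstrom).
#' @param enforce_resolution apply the resolution filter (default FALSE).
#' @param window_half default peptide half-window for the site table.
#' @return list of class `characterize_config`.
#' @export
characterize_config <- function(structure, sites, domains = NULL,
                                ligands = NULL, out_dir = "ptm3d_out",
                                radii = 2:12, theta_cutoff = 80,
                                hbond_cutoff = 3.5, salt_cutoff = 5.5,
                                vdw_cutoff = 5.0, pair_threshold = 5L,
                                contact_cutoff = 4.0, weak_cutoff = 12.0,
                                resolution_cutoff = 2.5,
                                enforce_resolution = FALSE,
                                window_half = 10L) {
  cfg <- list(structure = structure, sites = sites, domains = domains,
              ligands = ligands, out_dir = out_dir, radii = radii,
              theta_cutoff = theta_cutoff, hbond_cutoff = hbond_cutoff,
              salt_cutoff = salt_cutoff, vdw_cutoff = vdw_cutoff,
              pair_threshold = as.integer(pair_threshold),
              contact_cutoff = contact_cutoff, weak_cutoff = weak_cutoff,
              resolution_cutoff = resolution_cutoff,
              enforce_resolution = isTRUE(enforce_resolution),
              window_half = as.integer(window_half))
  num <- c("theta_cutoff", "hbond_cutoff", "salt_cutoff", "vdw_cutoff",
           "contact_cutoff", "weak_cutoff", "resolution_cutoff")
  for (k in num) stopifnot(cfg[[k]] > 0)
  stopifnot(all(cfg$radii > 0))
  class(cfg) <- "characterize_config"
  cfg
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full per-site characterization pipeline
#'
#' Maps the PTM sites onto the structure, then, for each uniquely mapped site,
#' computes the radial amino-acid composition, the acid/base division, the
#' side-chain orientation records of its spatial neighbors, and the surface /
#' secondary-structure summary; detects domain-domain interfaces and flags
#' sites on them; classifies sites against bound ligands. All results are
#' written as TSV files plus a JSON summary in `out_dir`; outputs are
#' deterministic (two runs on identical inputs are byte-identical).
#'
#' @param config a `characterize_config`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results and the paths written.
#' @export
run_characterize <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "characterize_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  for (p in c(config$structure, config$sites, config$domains,
              config$ligands)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- read_structure(config$structure)
  note("structure ", s$structure_id, ": ",
       nrow(residue_table(s)), " protein residues")
  if (config$enforce_resolution &&
      !passes_resolution_filter(s, config$resolution_cutoff)) {
    note("structure rejected by resolution filter (",
         ifelse(is.na(s$resolution), "no resolution", s$resolution),
         " vs cutoff ", config$resolution_cutoff, "); all sites skipped")
    sites <- read_ptm_sites(config$sites, config$window_half)[0L, ]
  } else {
    sites <- read_ptm_sites(config$sites, config$window_half)
  }
  mapped <- map_sites_batch(sites, s)
  write_tsv(mapped, file.path(config$out_dir, "mapping.tsv"))
  um <- mapped[!is.na(mapped$match_kind) & mapped$match_kind == "unique", ,
               drop = FALSE]
  for (i in seq_len(nrow(mapped))) {
    if (mapped$match_kind[i] != "unique") {
      note("site ", mapped$protein_id[i], ":", mapped$position[i],
           " not characterized (match_kind = ", mapped$match_kind[i], ")")
    }
  }
  if (nrow(um) == 0L) note("warning: zero uniquely mapped sites")

  site_label <- function(row) paste0(row$protein_id, ":", row$position)
  comp_rows <- list(); ab_rows <- list(); ori_rows <- list()
  surf_rows <- list()
  for (i in seq_len(nrow(um))) {
    site <- um[i, , drop = FALSE]
    lab <- site_label(site)
    rc <- radial_composition(site, s, radii = config$radii)
    tb <- radial_composition_table(rc)
    tb <- cbind(site = lab, tb, stringsAsFactors = FALSE)
    comp_rows[[i]] <- tb
    ab <- acid_base_division(site, s, radius = max(config$radii))
    ab_rows[[i]] <- cbind(site = lab, ab, stringsAsFactors = FALSE)
    fo <- functional_neighbors(site, s, radius = max(config$radii),
                               theta_cutoff = config$theta_cutoff)
    if (nrow(fo) > 0L) {
      ori_rows[[i]] <- cbind(site = lab, fo, stringsAsFactors = FALSE)
    }
    su <- site_surface_summary(site, s)
    surf_rows[[i]] <- cbind(site = lab, ptm_type = site$ptm_type, su,
                            stringsAsFactors = FALSE)
  }
  bindw <- function(rows, empty_names) {
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- as.data.frame(stats::setNames(
        replicate(length(empty_names), character(0), simplify = FALSE),
        empty_names))
    }
    out
  }
  write_tsv(bindw(comp_rows, c("site", "radius", "amino_acid", "count",
                               "freq")),
            file.path(config$out_dir, "radial_composition.tsv"))
  write_tsv(bindw(ab_rows, c("site", "radius", "n_acidic", "n_basic",
                             "n_neutral", "n_total")),
            file.path(config$out_dir, "acid_base.tsv"))
  write_tsv(bindw(ori_rows, c("site", "chain_id", "seq_num", "icode",
                              "res_name", "aa", "distance", "theta",
                              "is_functional")),
            file.path(config$out_dir, "orientation.tsv"))
  write_tsv(bindw(surf_rows, c("site", "ptm_type", "chain_id", "seq_num",
                               "icode", "ss", "sasa_complex",
                               "rel_acc_complex", "sasa_chain",
                               "rel_acc_chain", "flank_ss")),
            file.path(config$out_dir, "surface.tsv"))

  interfaces <- list()
  iface_rows <- list()
  ppi_rows <- list()
  if (!is.null(config$domains)) {
    domains <- read_domain_ranges(config$domains)
    prs <- enumerate_domain_pairs(domains)
    for (k in seq_len(nrow(prs))) {
      ir <- detect_interface(
        s, domains[prs$a[k], , drop = FALSE], domains[prs$b[k], , drop = FALSE],
        hbond_cutoff = config$hbond_cutoff, salt_cutoff = config$salt_cutoff,
        vdw_cutoff = config$vdw_cutoff,
        pair_threshold = config$pair_threshold)
      interfaces[[length(interfaces) + 1L]] <- ir
      iface_rows[[k]] <- data.frame(
        domain_a = ir$domain_a$domain_name, chain_a = ir$domain_a$chain_id,
        domain_b = ir$domain_b$domain_name, chain_b = ir$domain_b$chain_id,
        n_pairs = ir$n_pairs, is_interaction = ir$is_interaction,
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(nrow(um))) {
      site <- um[i, , drop = FALSE]
      v <- classify_site_ppi(site, interfaces)
      ppi_rows[[i]] <- data.frame(
        site = site_label(site), ptm_type = site$ptm_type,
        on_interface = v$on_interface,
        interfaces = paste(v$interfaces, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  write_tsv(bindw(iface_rows, c("domain_a", "chain_a", "domain_b", "chain_b",
                                "n_pairs", "is_interaction")),
            file.path(config$out_dir, "interfaces.tsv"))
  write_tsv(bindw(ppi_rows, c("site", "ptm_type", "on_interface",
                              "interfaces")),
            file.path(config$out_dir, "ppi_sites.tsv"))

  annotations <- if (!is.null(config$ligands)) {
    read_ligand_annotations(config$ligands)
  } else NULL
  drug <- site_drug_report(um, s, annotations,
                           contact_cutoff = config$contact_cutoff,
                           weak_cutoff = config$weak_cutoff)
  write_tsv(drug$per_site, file.path(config$out_dir, "drug_associations.tsv"))
  write_tsv(drug$summary, file.path(config$out_dir, "drug_summary.tsv"))

  summary <- list(
    structure_id = s$structure_id,
    resolution = if (is.na(s$resolution)) NULL else s$resolution,
    n_sites = nrow(mapped),
    n_unique = sum(mapped$match_kind == "unique"),
    n_ambiguous = sum(mapped$match_kind == "ambiguous"),
    n_unmapped = sum(mapped$match_kind == "none"),
    n_interfaces = length(interfaces),
    n_interactions = sum(vapply(interfaces, function(x) x$is_interaction,
                                logical(1L))),
    n_sites_on_interface = sum(vapply(ppi_rows, function(r) r$on_interface,
                                      logical(1L))),
    drug_summary = drug$summary
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(structure = s, mapped = mapped, interfaces = interfaces,
                 drug = drug, summary = summary, out_dir = config$out_dir))
}
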