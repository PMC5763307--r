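# Mapping of experimentally verified PTM peptides onto structure chains by
# exact (100% identity, gap-free) sequence matching.

#' Construct a PTM site record
#'
#' A PTM site is an experimentally verified modification described by its
#' protein, 1-based position, modification type, expected residue and a
#' flanking peptide window centered on the site (a 21-mer for the default
#' `window_half = 10`, shorter when truncated at the protein termini).
#'
#' @param protein_id protein identifier string.
#' @param position 1-based position of the modified residue in the protein.
#' @param ptm_type modification type (e.g. `"phosphorylation"`).
#' @param residue expected one-letter amino-acid code of the modified residue.
#' @param peptide flanking window string containing the site.
#' @param window_half half-window length (default 10).
#' @return one-row data.frame of class `ptm_site_table`.
#' @export
#' @examples
#' ptm_site("P1", 6, "phosphorylation", "S", "AAAAASAAAAA", window_half = 5)
ptm_site <- function(protein_id, position, ptm_type, residue, peptide,
                     window_half = 10L) {
  stopifnot(position >= 1L, nchar(residue) == 1L)
  peptide <- toupper(peptide)
  center <- peptide_center_index(position, window_half)
  if (center > nchar(peptide)) {
    stop("peptide shorter than its own site index")
  }
  if (substr(peptide, center, center) != toupper(residue)) {
    stop("peptide center ('", substr(peptide, center, center),
         "') does not match the expected residue code ('", residue, "')")
  }
  out <- data.frame(
    protein_id = protein_id, position = as.integer(position),
    ptm_type = tolower(ptm_type), residue = toupper(residue),
    peptide = peptide, window_half = as.integer(window_half),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ptm_site_table", "data.frame")
  out
}

# Index of the modified residue inside a (possibly left-truncated) window.
#' @keywords internal
peptide_center_index <- function(position, window_half) {
  if (position <= window_half) position else window_half + 1L
}

#' Read PTM sites from a TSV file
#'
#' Expected header: protein_id, position, ptm_type, residue, peptide (and
#' optionally window_half).
#'
#' @param path TSV file path.
#' @param window_half default half-window when the file carries none.
#' @return data.frame of validated sites.
#' @export
read_ptm_sites <- function(path, window_half = 10L) {
  if (!file.exists(path)) stop("PTM site file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(protein_id = "character",
                                         ptm_type = "character",
                                         residue = "character",
                                         peptide = "character"))
  need <- c("protein_id", "position", "ptm_type", "residue", "peptide")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("PTM site table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    out <- ptm_site("x", 3L, "phosphorylation", "S", "AASAA", 2L)[0L, ]
    return(out)
  }
  if (!"window_half" %in% names(df)) df$window_half <- as.integer(window_half)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ptm_site(df$protein_id[i], df$position[i], df$ptm_type[i],
             df$residue[i], df$peptide[i], df$window_half[i])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ptm_site_table", "data.frame")
  out
}

#' Map a PTM peptide onto one chain by exact identity
#'
#' Searches for exact, gap-free occurrences of the peptide in the chain's
#' coordinate-derived sequence. A unique occurrence maps the peptide's site
#' residue onto a structural residue; multiple occurrences are reported as
#' `ambiguous` (no residue assigned) and zero occurrences as `none`. An
#' occurrence is discarded when it spans a numbering gap (unresolved residues),
#' so sites in unresolved regions correctly fail to map.
#'
#' @param site one-row PTM site data.frame (see [ptm_site()]).
#' @param s a `ptm_structure`.
#' @param chain_id chain to search.
#' @return one-row data.frame: the site columns plus structure_id, chain_id,
#'   seq_num, icode, match_kind (`"unique"`, `"ambiguous"` or `"none"`).
#' @export
map_peptide <- function(site, s, chain_id) {
  site <- as.data.frame(site)
  stopifnot(nrow(site) == 1L)
  if (nchar(site$peptide) < 5L) {
    stop("peptide shorter than 5 residues is an uninformative window")
  }
  cs <- chain_sequence(s, chain_id)
  center <- peptide_center_index(site$position, site$window_half)
  hits <- find_contiguous_occurrences(site$peptide, cs)
  res <- data.frame(
    site, structure_id = s$structure_id, chain_id = chain_id,
    seq_num = NA_integer_, icode = NA_character_,
    match_kind = "none", stringsAsFactors = FALSE
  )
  if (length(hits) == 1L) {
    pos <- hits[1L] + center - 1L
    res$seq_num <- cs$map$seq_num[pos]
    res$icode <- cs$map$icode[pos]
    res$match_kind <- "unique"
  } else if (length(hits) > 1L) {
    res$match_kind <- "ambiguous"
  }
  res
}

# Occurrence start positions of peptide in the chain sequence, keeping only
# matches whose residue numbering is contiguous in author order (consecutive
# seq_num, or equal seq_num with differing insertion codes).
#' @keywords internal
find_contiguous_occurrences <- function(peptide, cs) {
  # lookahead so that overlapping occurrences (repeat sequences) are found
  pat <- paste0("(?=", gsub("([^A-Za-z0-9])", "\\\\\\1", peptide), ")")
  hits <- gregexpr(pat, cs$sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  len <- nchar(peptide)
  keep <- vapply(hits, function(h) {
    span <- seq.int(h, h + len - 1L)
    if (length(span) < 2L) return(TRUE)
    dn <- diff(cs$map$seq_num[span])
    same <- dn == 0L &
      cs$map$icode[span[-length(span)]] != cs$map$icode[span[-1L]]
    all(dn == 1L | same)
  }, logical(1L))
  as.integer(hits[keep])
}

#' Map a batch of PTM sites onto all chains of a structure
#'
#' Each site is matched against every chain; the best result per site is kept
#' with preference unique > ambiguous > none, ties broken by ascending
#' chain_id.
#'
#' @param sites PTM site data.frame (zero or more rows).
#' @param s a `ptm_structure`.
#' @return data.frame of mapped sites, one row per input site (empty for an
#'   empty input).
#' @export
map_sites_batch <- function(sites, s) {
  sites <- as.data.frame(sites)
  chains <- sort(unique(residue_table(s)$chain_id))
  if (nrow(sites) == 0L) {
    out <- map_peptide(ptm_site("x", 3L, "phosphorylation", "S", "AASAA",
                                window_half = 2L), s, chains[1L])[0L, ]
    return(out)
  }
  rank <- c(unique = 1L, ambiguous = 2L, none = 3L)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    cand <- lapply(chains, function(ch) {
      map_peptide(sites[i, , drop = FALSE], s, ch)
    })
    scores <- vapply(cand, function(m) rank[[m$match_kind]], integer(1L))
    cand[[which.min(scores)]]  # which.min keeps the first (lowest chain_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write mapped sites as TSV
#'
#' @param mapped data.frame from [map_sites_batch()].
#' @param path output file path.
#' @export
write_mapped_sites <- function(mapped, path) {
  utils::write.table(mapped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Shared guard used by all per-site structural computations.
#' @keywords internal
assert_unique_mapping <- function(site) {
  site <- as.data.frame(site)
  stopifnot(nrow(site) == 1L)
  if (!identical(site$match_kind, "unique")) {
    stop("site is not uniquely mapped (match_kind = ", site$match_kind, ")")
  }
  site
}
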