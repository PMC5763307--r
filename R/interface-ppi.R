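# Domain-domain interaction interfaces between subunits: typed residue-residue
# contacts (hydrogen bond N-O <= 3.5 A; salt bridge charged-group N-O <= 5.5 A;
# van der Waals C-C <= 5.0 A) and the "more than five contacting residue
# pairs" interaction rule.

#' Construct a domain range
#'
#' @param chain_id chain identifier.
#' @param start,end inclusive author residue numbers, start <= end.
#' @param domain_name domain label.
#' @return one-row data.frame.
#' @export
domain_range <- function(chain_id, start, end, domain_name = "domain") {
  stopifnot(start <= end)
  data.frame(chain_id = chain_id, start = as.integer(start),
             end = as.integer(end), domain_name = domain_name,
             stringsAsFactors = FALSE)
}

#' Read domain ranges from TSV
#'
#' Expected header: chain_id, start, end, domain_name.
#'
#' @param path TSV file path.
#' @return data.frame of domain ranges.
#' @export
read_domain_ranges <- function(path) {
  if (!file.exists(path)) stop("domain file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chain_id = "character"))
  need <- c("chain_id", "start", "end", "domain_name")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("domain table missing column(s): ", paste(miss, collapse = ", "))
  }
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    domain_range(df$chain_id[i], df$start[i], df$end[i], df$domain_name[i])
  }))
}

#' @keywords internal
domain_atoms <- function(s, dom) {
  a <- heavy_atoms(s$atoms)
  a <- a[protein_mask(a), , drop = FALSE]
  a[a$chain_id == dom$chain_id & a$seq_num >= dom$start &
      a$seq_num <= dom$end, , drop = FALSE]
}

# Names of atoms admitted to the charged-group salt-bridge criterion.
#' @keywords internal
salt_atom_mask <- function(atoms, role = c("basic", "acidic")) {
  role <- match.arg(role)
  tab <- if (role == "basic") SALT_BASIC_ATOMS else SALT_ACIDIC_ATOMS
  ok <- rep(FALSE, nrow(atoms))
  for (res in names(tab)) {
    ok <- ok | (toupper(atoms$res_name) == res & atoms$atom_name %in% tab[[res]])
  }
  if (role == "acidic") ok <- ok | atoms$atom_name == "OXT"  # C-terminus
  ok
}

#' Typed residue contacts between two domains
#'
#' A residue pair (one residue in each domain, domains on different chains) is
#' in contact when any criterion holds: some N-O atom pair within 3.5 A
#' (hydrogen bond); some charged-group N-O pair within 5.5 A with one side
#' acidic and the other basic (salt bridge); or some C-C pair within 5.0 A
#' (van der Waals). A pair may carry several kinds but counts once toward the
#' interface threshold.
#'
#' @param s a `ptm_structure`.
#' @param dom_a,dom_b one-row domain ranges on different chains.
#' @param hbond_cutoff,salt_cutoff,vdw_cutoff distance cutoffs in Angstrom
#'   (defaults 3.5, 5.5, 5.0; all inclusive).
#' @param method neighbor-search method, `"grid"` or `"brute"`.
#' @return data.frame with one row per (residue pair, kind): chain_a, seq_a,
#'   icode_a, resn_a, chain_b, seq_b, icode_b, resn_b, kind, distance (minimum
#'   qualifying atom distance for that kind).
#' @export
detect_contacts <- function(s, dom_a, dom_b, hbond_cutoff = 3.5,
                            salt_cutoff = 5.5, vdw_cutoff = 5.0,
                            method = c("grid", "brute")) {
  method <- match.arg(method)
  if (dom_a$chain_id == dom_b$chain_id) {
    stop("domains must lie on different chains")
  }
  aa <- domain_atoms(s, dom_a)
  ab <- domain_atoms(s, dom_b)
  empty <- data.frame(
    chain_a = character(0), seq_a = integer(0), icode_a = character(0),
    resn_a = character(0), chain_b = character(0), seq_b = integer(0),
    icode_b = character(0), resn_b = character(0), kind = character(0),
    distance = numeric(0), stringsAsFactors = FALSE
  )
  if (nrow(aa) == 0L || nrow(ab) == 0L) return(empty)
  maxcut <- max(hbond_cutoff, salt_cutoff, vdw_cutoff)
  prs <- neighbor_pairs(atom_xyz(aa), atom_xyz(ab), maxcut, method = method)
  if (nrow(prs) == 0L) return(empty)
  ea <- aa$element[prs$i]; eb <- ab$element[prs$j]
  hbond <- ((ea == "N" & eb == "O") | (ea == "O" & eb == "N")) &
    prs$dist <= hbond_cutoff
  basic_a <- salt_atom_mask(aa, "basic")[prs$i]
  basic_b <- salt_atom_mask(ab, "basic")[prs$j]
  acid_a <- salt_atom_mask(aa, "acidic")[prs$i]
  acid_b <- salt_atom_mask(ab, "acidic")[prs$j]
  salt <- ((basic_a & acid_b) | (acid_a & basic_b)) & prs$dist <= salt_cutoff
  vdw <- ea == "C" & eb == "C" & prs$dist <= vdw_cutoff
  rows <- list()
  for (kind in c("hbond", "salt_bridge", "vdw")) {
    sel <- switch(kind, hbond = hbond, salt_bridge = salt, vdw = vdw)
    if (!any(sel)) next
    sub <- prs[sel, , drop = FALSE]
    key <- paste(aa$seq_num[sub$i], aa$icode[sub$i],
                 ab$seq_num[sub$j], ab$icode[sub$j], sep = "\r")
    best <- tapply(seq_len(nrow(sub)), key, function(k) {
      k[which.min(sub$dist[k])]
    })
    sub <- sub[as.integer(best), , drop = FALSE]
    rows[[kind]] <- data.frame(
      chain_a = aa$chain_id[sub$i], seq_a = aa$seq_num[sub$i],
      icode_a = aa$icode[sub$i], resn_a = aa$res_name[sub$i],
      chain_b = ab$chain_id[sub$j], seq_b = ab$seq_num[sub$j],
      icode_b = ab$icode[sub$j], resn_b = ab$res_name[sub$j],
      kind = kind, distance = sub$dist, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$seq_a, out$icode_a, out$seq_b, out$icode_b, out$kind), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface verdict for a domain pair
#'
#' Two domains on different chains form an interaction interface when the
#' number of distinct contacting residue pairs exceeds `pair_threshold`
#' (default 5, i.e. at least 6 pairs).
#'
#' @inheritParams detect_contacts
#' @param pair_threshold interaction requires strictly more than this many
#'   distinct residue pairs (default 5).
#' @return list of class `interface_result`: `domain_a`, `domain_b`,
#'   `contacts` (from [detect_contacts()]), `n_pairs` (distinct residue
#'   pairs), `is_interaction`, `contact_residues` (data.frame of chain_id,
#'   seq_num, icode over both sides).
#' @export
detect_interface <- function(s, dom_a, dom_b, hbond_cutoff = 3.5,
                             salt_cutoff = 5.5, vdw_cutoff = 5.0,
                             pair_threshold = 5L,
                             method = c("grid", "brute")) {
  contacts <- detect_contacts(s, dom_a, dom_b, hbond_cutoff, salt_cutoff,
                              vdw_cutoff, method = method)
  pair_key <- unique(paste(contacts$seq_a, contacts$icode_a, contacts$seq_b,
                           contacts$icode_b, sep = "\r"))
  n_pairs <- length(pair_key)
  cres <- unique(rbind(
    data.frame(chain_id = contacts$chain_a, seq_num = contacts$seq_a,
               icode = contacts$icode_a, stringsAsFactors = FALSE),
    data.frame(chain_id = contacts$chain_b, seq_num = contacts$seq_b,
               icode = contacts$icode_b, stringsAsFactors = FALSE)
  ))
  rownames(cres) <- NULL
  structure(
    list(domain_a = dom_a, domain_b = dom_b, contacts = contacts,
         n_pairs = n_pairs, is_interaction = n_pairs > pair_threshold,
         contact_residues = cres),
    class = "interface_result"
  )
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf("interface %s[%d-%d] x %s[%d-%d]: %d contacting pairs -> %s\n",
              x$domain_a$chain_id, x$domain_a$start, x$domain_a$end,
              x$domain_b$chain_id, x$domain_b$start, x$domain_b$end,
              x$n_pairs,
              if (x$is_interaction) "interaction" else "no interaction"))
  invisible(x)
}

#' All cross-chain domain pairs
#'
#' @param domains data.frame of domain ranges.
#' @return data.frame with columns `a` and `b` (row indices into `domains`),
#'   every unordered pair of domains on distinct chains, in deterministic
#'   (row-order) sequence; empty when fewer than two chains are present.
#' @export
enumerate_domain_pairs <- function(domains) {
  n <- nrow(domains)
  out <- data.frame(a = integer(0), b = integer(0))
  if (is.null(n) || n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (domains$chain_id[i] != domains$chain_id[j]) {
        out <- rbind(out, data.frame(a = i, b = j))
      }
    }
  }
  out
}

#' Is a mapped site located on a PPI interface?
#'
#' A site is on an interface when its mapped residue belongs to the contact
#' residues of any supplied interface result.
#'
#' @param site uniquely mapped site row.
#' @param interfaces list of `interface_result` objects.
#' @return list: `on_interface` flag and `interfaces`, the integer indices of
#'   the implicated interface results.
#' @export
classify_site_ppi <- function(site, interfaces) {
  site <- assert_unique_mapping(site)
  hit <- integer(0)
  for (k in seq_along(interfaces)) {
    cr <- interfaces[[k]]$contact_residues
    if (nrow(cr) == 0L) next
    if (any(cr$chain_id == site$chain_id & cr$seq_num == site$seq_num &
              cr$icode == site$icode)) {
      hit <- c(hit, k)
    }
  }
  list(on_interface = length(hit) > 0L, interfaces = hit)
}
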