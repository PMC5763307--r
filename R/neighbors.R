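# Pairwise neighbor search between two atom sets, with a cell-list (grid)
# acceleration and a brute-force reference path. Both return the identical
# pair set; tests assert the equivalence on random structures.

#' Atom pairs within a distance cutoff
#'
#' Finds all pairs (i, j) with `i` indexing rows of `xyz_a`, `j` rows of
#' `xyz_b`, whose Euclidean distance is `<= cutoff`.
#'
#' @param xyz_a,xyz_b numeric matrices with 3 columns (Angstrom coordinates).
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param method `"grid"` (cell list, default) or `"brute"` (all-pairs scan).
#' @return data.frame with columns `i`, `j`, `dist`, ordered by (i, j).
#' @export
neighbor_pairs <- function(xyz_a, xyz_b, cutoff,
                           method = c("grid", "brute")) {
  method <- match.arg(method)
  xyz_a <- as.matrix(xyz_a)
  xyz_b <- as.matrix(xyz_b)
  stopifnot(ncol(xyz_a) == 3L, ncol(xyz_b) == 3L, cutoff > 0)
  if (nrow(xyz_a) == 0L || nrow(xyz_b) == 0L) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  out <- if (method == "brute") {
    d <- cross_distances(xyz_a, xyz_b)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    data.frame(i = hit[, 1L], j = hit[, 2L],
               dist = d[hit], stringsAsFactors = FALSE)
  } else {
    grid_pairs(xyz_a, xyz_b, cutoff)
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
grid_pairs <- function(xyz_a, xyz_b, cutoff) {
  cell <- cutoff
  cb <- floor(xyz_b / cell)
  keyb <- paste(cb[, 1L], cb[, 2L], cb[, 3L], sep = ",")
  bins <- split(seq_len(nrow(xyz_b)), keyb)
  ca <- floor(xyz_a / cell)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  is <- integer(0); js <- integer(0); ds <- numeric(0)
  for (i in seq_len(nrow(xyz_a))) {
    keys <- paste(ca[i, 1L] + off[, 1L], ca[i, 2L] + off[, 2L],
                  ca[i, 3L] + off[, 3L], sep = ",")
    cand <- unlist(bins[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    dv <- sqrt(colSums((t(xyz_b[cand, , drop = FALSE]) - xyz_a[i, ])^2))
    hit <- dv <= cutoff
    if (any(hit)) {
      is <- c(is, rep.int(i, sum(hit)))
      js <- c(js, cand[hit])
      ds <- c(ds, dv[hit])
    }
  }
  data.frame(i = is, j = js, dist = ds, stringsAsFactors = FALSE)
}
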