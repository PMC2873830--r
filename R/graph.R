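# Cutoff distance graphs and the per-atom adjacency index that makes the
# RUGB base search O(d_max^3) per atom instead of a search over all atoms.

#' Build a sparse distance set from a structure with a cutoff
#'
#' Keeps exactly the unordered atom pairs whose Euclidean distance is at
#' most `cutoff`, with the full double-precision distance. This emulates the
#' NMR-style situation where only short inter-atomic distances (typically
#' below 5 Angstrom) are observable.
#'
#' @param structure a [structure3d()].
#' @param cutoff distance cutoff in Angstrom (`Inf` for the complete set).
#' @return A [sparse_distance_set()].
#' @export
build_distance_set <- function(structure, cutoff) {
  if (!is.finite(cutoff) && cutoff != Inf)
    stop_geobuild("geobuild_parse_error", "cutoff must be positive")
  if (cutoff <= 0)
    stop_geobuild("geobuild_parse_error", "cutoff must be positive")
  co <- structure$coords
  n <- nrow(co)
  dm <- as.matrix(stats::dist(co))
  keep <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  sparse_distance_set(keep[, 1L], keep[, 2L], dm[keep], n = n)
}

#' Build the per-atom adjacency index of a sparse distance set
#'
#' For every atom, the array of its neighbours (atoms with a known distance
#' to it), sorted by neighbour id, plus the degrees and the maximum degree
#' `d_max`. Base searches that walk only these arrays cost O(d_max^3) per
#' atom, which is the data-structure contribution of the revised build-up.
#'
#' @param dset a [sparse_distance_set()].
#' @return Object of class `"adjacency_index"`: list with `n`,
#'   `neighbours` (per-atom list of `list(id=, d=)` vectors sorted by id),
#'   `degrees`, `d_max`, and a dense symmetric lookup matrix `dmat`
#'   (0 = no known distance).
#' @export
build_adjacency_index <- function(dset) {
  n <- dset$n
  e <- dset$entries
  dmat <- matrix(0, n, n)
  if (nrow(e) > 0) {
    dmat[cbind(e$i, e$j)] <- e$d
    dmat[cbind(e$j, e$i)] <- e$d
  }
  neighbours <- vector("list", n)
  for (a in seq_len(n)) {
    nb <- which(dmat[, a] > 0)
    neighbours[[a]] <- list(id = nb, d = dmat[nb, a])
  }
  degrees <- vapply(neighbours, function(x) length(x$id), integer(1))
  structure(list(n = n, neighbours = neighbours, degrees = degrees,
                 d_max = if (n > 0) max(degrees, 0L) else 0L, dmat = dmat),
            class = "adjacency_index")
}

#' Convert an adjacency index back to its sparse distance set
#'
#' Exact inverse of [build_adjacency_index()].
#' @param idx an `"adjacency_index"`.
#' @return A [sparse_distance_set()].
#' @export
adjacency_to_distance_set <- function(idx) {
  keep <- which(upper.tri(idx$dmat) & idx$dmat > 0, arr.ind = TRUE)
  sparse_distance_set(keep[, 1L], keep[, 2L], idx$dmat[keep], n = idx$n)
}

#' Degree statistics of a distance graph
#'
#' @param idx an `"adjacency_index"`.
#' @return List with `n` (atom count), `d_max` (maximum degree), and
#'   `ratio` (`d_max / n`), the three columns of a sparsity report.
#' @export
degree_stats <- function(idx) {
  list(n = idx$n, d_max = idx$d_max,
       ratio = if (idx$n > 0) idx$d_max / idx$n else 0)
}

#' Look up a pairwise distance
#'
#' @param idx an `"adjacency_index"`.
#' @param i,j atom ids.
#' @return The stored distance, or `NA` if the pair is not in the set.
#'   Symmetric in `i`, `j`.
#' @export
has_distance <- function(idx, i, j) {
  if (i < 1L || j < 1L || i > idx$n || j > idx$n)
    stop_geobuild("geobuild_parse_error", "atom id out of range")
  d <- idx$dmat[i, j]
  if (d > 0) d else NA_real_
}
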