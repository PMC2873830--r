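# Core containers shared by every solver. Plain S3 over base matrices and
# data frames, in the style of bio3d objects. Atom ids are 1-based
# internally (the R convention); all file formats are 1-based as well.

#' Ordered atom list with 3D coordinates
#'
#' The ground-truth container and the reconstruction output: `n` atoms, each
#' with a finite 3-vector of coordinates in Angstrom. Optional per-atom
#' labels (atom name, residue, ...) are carried through from PDB input but
#' never interpreted.
#'
#' @param coords numeric `n x 3` matrix of coordinates (Angstrom).
#' @param labels optional data frame with `n` rows of atom annotations.
#' @return An object of class `"structure3d"`: a list with elements
#'   `coords` and `labels`.
#' @examples
#' s <- structure3d(matrix(rnorm(15), 5, 3))
#' n_atoms(s)
#' @export
structure3d <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop_geobuild("geobuild_parse_error", "coords must have 3 columns")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop_geobuild("geobuild_parse_error", "all coordinates must be finite")
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (nrow(labels) != nrow(coords))
      stop_geobuild("geobuild_parse_error", "labels must have one row per atom")
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, labels = labels), class = "structure3d")
}

#' @rdname structure3d
#' @param x a `structure3d` object.
#' @export
n_atoms <- function(x) nrow(x$coords)

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms\n", n_atoms(x)))
  invisible(x)
}

#' Sparse set of exact inter-atomic distances
#'
#' The molecular distance geometry problem instance: each unordered atom pair
#' `(i, j)` with a known exact distance is stored once with `i < j`.
#'
#' @param i,j integer atom ids (1-based); pairs are normalised to `i < j`.
#' @param d positive distances in Angstrom.
#' @param n total atom count (must cover all ids).
#' @return Object of class `"sparse_dist_set"`: list with `n` and a data
#'   frame `entries` with columns `i`, `j`, `d` sorted by `(i, j)`.
#' @examples
#' sparse_distance_set(c(1, 2), c(2, 3), c(4, 4), n = 3)
#' @export
sparse_distance_set <- function(i, j, d, n) {
  i <- as.integer(i); j <- as.integer(j); d <- as.numeric(d)
  n <- as.integer(n)
  if (length(i) != length(j) || length(i) != length(d))
    stop_geobuild("geobuild_parse_error", "i, j, d must have equal length")
  if (any(i == j))
    stop_geobuild("geobuild_parse_error", "self-pairs (i == j) are not allowed")
  if (any(i < 1L) || any(j < 1L) || any(i > n) || any(j > n))
    stop_geobuild("geobuild_parse_error", "atom ids out of range 1..n")
  if (any(!is.finite(d)) || any(d <= 0))
    stop_geobuild("geobuild_parse_error", "distances must be positive and finite")
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  key <- (i - 1) * as.double(n) + j
  if (anyDuplicated(key))
    stop_geobuild("geobuild_parse_error", "duplicate atom pairs in distance set")
  ord <- order(i, j)
  entries <- data.frame(i = i[ord], j = j[ord], d = d[ord])
  structure(list(n = n, entries = entries), class = "sparse_dist_set")
}

#' @export
print.sparse_dist_set <- function(x, ...) {
  cat(sprintf("sparse_dist_set: %d atoms, %d distances\n", x$n, nrow(x$entries)))
  invisible(x)
}

#' Metric base used to place one unpositioned atom
#'
#' Either four non-coplanar positioned atoms (GB/UGB), or three non-collinear
#' positioned atoms plus a disambiguating fourth atom that is not coplanar
#' with them (RUGB).
#'
#' @param base_ids 3 or 4 positioned atom ids.
#' @param base_coords matrix of their current global coordinates (rows match
#'   `base_ids`).
#' @param extra_id optional disambiguating atom id (RUGB 3-atom base only).
#' @param extra_coord its current global coordinate.
#' @return Object of class `"metric_base"`.
#' @export
metric_base <- function(base_ids, base_coords, extra_id = NULL, extra_coord = NULL) {
  base_ids <- as.integer(base_ids)
  base_coords <- as.matrix(base_coords)
  if (!length(base_ids) %in% c(3L, 4L))
    stop_geobuild("geobuild_parse_error", "a metric base has 3 or 4 atoms")
  if (nrow(base_coords) != length(base_ids))
    stop_geobuild("geobuild_parse_error", "base_coords rows must match base_ids")
  if (length(base_ids) == 3L && is.null(extra_id))
    stop_geobuild("geobuild_parse_error", "a 3-atom base requires a disambiguating extra atom")
  structure(list(base_ids = base_ids, base_coords = base_coords,
                 extra_id = if (is.null(extra_id)) NULL else as.integer(extra_id),
                 extra_coord = extra_coord),
            class = "metric_base")
}

#' Reconstruction output of a build-up solver
#'
#' @param structure `structure3d` with coordinates for positioned atoms
#'   (rows of unpositioned atoms are `NA`).
#' @param positioned logical mask over atoms.
#' @param status one of `"complete"`, `"partial"`, `"failed"`.
#' @param provenance data frame recording, for every atom placed beyond the
#'   initial base: atom id, sweep number, placement method, base atom ids.
#' @param restart_count number of initial bases tried.
#' @return Object of class `"recon_result"`.
#' @export
reconstruction_result <- function(structure, positioned, status, provenance,
                                  restart_count) {
  status <- match.arg(status, c("complete", "partial", "failed"))
  if (status == "complete" && !all(positioned))
    stop_geobuild("geobuild_parse_error", "status complete requires all atoms positioned")
  structure(list(structure = structure, positioned = positioned, status = status,
                 provenance = provenance, restart_count = restart_count),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("recon_result: status %s, %d/%d atoms positioned, %d restart(s)\n",
              x$status, sum(x$positioned), length(x$positioned), x$restart_count))
  invisible(x)
}
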