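# Rigid superposition kernels used by the updating ("re-initializing") step
# and by evaluation. The optimal orthogonal map is the classic Procrustes
# solution via SVD; an improper map (det = -1) is deliberately permitted,
# because a freshly initialized canonical tetrahedron may be the mirror image
# of the placed one and only an improper map can carry it onto the old base.

#' Centre a point set at the origin
#'
#' @param points `n x 3` coordinate matrix.
#' @return List with `centered` (the translated matrix) and `centroid`
#'   (arithmetic mean of the rows).
#' @export
center_points <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L)
    stop_geobuild("geobuild_parse_error", "center_points needs at least one point")
  centroid <- colMeans(points)
  list(centered = sweep(points, 2L, centroid), centroid = centroid)
}

#' Optimal orthogonal map between two centred point sets
#'
#' Returns the orthogonal matrix `Q` minimising the Frobenius norm
#' `||X1 - Y1 Q||` over all orthogonal matrices, computed as `Q = U V^T`
#' from the singular value decomposition `U S V^T` of `C = Y1^T X1`.
#' `Q` may be improper (`det(Q) = -1`) when the two sets are mirror images.
#'
#' @param X1 centred target point set (`n x 3`).
#' @param Y1 centred source point set (`n x 3`), same row count.
#' @return 3x3 orthogonal matrix. When `C` has rank < 2 the rotation is not
#'   unique; a warning of class `geobuild_rank_deficient` is raised and the
#'   SVD's deterministic output is returned.
#' @export
optimal_rotation <- function(X1, Y1) {
  X1 <- as.matrix(X1); Y1 <- as.matrix(Y1)
  if (nrow(X1) != nrow(Y1))
    stop_geobuild("geobuild_mismatched_atoms", "point sets differ in size")
  C <- crossprod(Y1, X1)
  s <- svd(C)
  if (sum(s$d > 1e-12 * max(s$d, .Machine$double.xmin)) < 2L)
    warning(warningCondition("rotation is not unique (rank-deficient cross-covariance)",
                             class = "geobuild_rank_deficient"))
  s$u %*% t(s$v)
}

#' Root-mean-square deviation between paired point sets
#'
#' @param X,Y `n x 3` matrices with rows in correspondence.
#' @return `sqrt(mean(||X_i - Y_i||^2))` in Angstrom.
#' @export
rmsd_points <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop_geobuild("geobuild_mismatched_atoms", "point sets differ in size")
  sqrt(mean(rowSums((X - Y)^2)))
}

#' Map a freshly initialized base (plus new atoms) back into the structure
#'
#' The updating step of UGB/RUGB: the base atoms are re-computed in a
#' canonical local frame from original distances, then the whole fresh
#' complex (base first, newly determined atom(s) after) is rigidly mapped
#' onto the old global base positions. The mapped base coordinates replace
#' the old ones, stopping error accumulation.
#'
#' @param old_base_coords `k x 3` current global coordinates of the base
#'   atoms (k = 3 or 4).
#' @param fresh_local_coords `m x 3` local coordinates, the k base atoms
#'   first, any newly determined atoms after.
#' @return `m x 3` matrix of global coordinates for all fresh atoms.
#' @export
reinsert <- function(old_base_coords, fresh_local_coords) {
  old_base_coords <- as.matrix(old_base_coords)
  fresh_local_coords <- as.matrix(fresh_local_coords)
  k <- nrow(old_base_coords)
  if (nrow(fresh_local_coords) < k)
    stop_geobuild("geobuild_parse_error",
                  "fresh coordinates must contain the base atoms first")
  co <- center_points(old_base_coords)
  cf <- center_points(fresh_local_coords[seq_len(k), , drop = FALSE])
  Q <- optimal_rotation(co$centered, cf$centered)
  sweep(fresh_local_coords, 2L, cf$centroid) %*% Q +
    matrix(co$centroid, nrow(fresh_local_coords), 3L, byrow = TRUE)
}
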