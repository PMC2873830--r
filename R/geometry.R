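# Exact placement kernels. Everything here works in plain double precision
# on exact input distances; tolerances exist only to detect degeneracy and
# corrupted inputs, not to absorb measurement noise.

#' Degeneracy test for 3 or 4 points
#'
#' Four points are degenerate when coplanar, three when collinear. The test
#' is scale-invariant: for four points the determinant of the three edge
#' vectors from the first point is compared against `rel_tol` times the
#' product of the edge norms; for three points the cross-product norm is
#' compared against `rel_tol` times the product of the two edge norms.
#'
#' @param coords 3x3 or 4x3 coordinate matrix.
#' @param rel_tol relative tolerance (default `1e-8`; near-flat tetrahedra
#'   below this are treated as degenerate because they amplify placement
#'   error catastrophically).
#' @return `TRUE` if degenerate.
#' @examples
#' is_degenerate(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))  # FALSE
#' is_degenerate(rbind(c(0,0,0), c(1,0,0), c(2,0,0)))            # TRUE
#' @export
is_degenerate <- function(coords, rel_tol = 1e-8) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (m == 4L) {
    e <- coords[2:4, , drop = FALSE] - matrix(coords[1, ], 3, 3, byrow = TRUE)
    nrm <- sqrt(rowSums(e^2))
    scale <- prod(nrm)
    if (scale == 0) return(TRUE)
    abs(det(e)) <= rel_tol * scale
  } else if (m == 3L) {
    v1 <- coords[2, ] - coords[1, ]
    v2 <- coords[3, ] - coords[1, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    scale <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
    if (scale == 0) return(TRUE)
    sqrt(sum(cr^2)) <= rel_tol * scale
  } else {
    stop_geobuild("geobuild_parse_error", "is_degenerate expects 3 or 4 points")
  }
}

#' Place a point from four positioned reference points (trilateration)
#'
#' Solves the sphere-intersection system for a point at known distances from
#' four non-coplanar reference points. Squaring the four sphere equations and
#' subtracting the first from the rest leaves a nonsingular 3x3 linear
#' system, so the solution is unique and found by one linear solve.
#'
#' @param base_coords 4x3 matrix of reference coordinates.
#' @param dists length-4 vector of distances from the unknown point to each
#'   reference point (Angstrom).
#' @param tol residual tolerance in Angstrom: after solving, the absolute
#'   mismatch between each requested distance and the achieved one must not
#'   exceed `tol` (use `Inf` to disable, e.g. when the base coordinates
#'   themselves carry accumulated error).
#' @param rel_tol degeneracy tolerance passed to [is_degenerate()].
#' @return The placed point as a length-3 vector with attribute
#'   `"residuals"` (the four absolute distance mismatches).
#' @examples
#' base <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
#' p <- c(0.3, 0.2, 0.4)
#' trilaterate4(base, sqrt(colSums((t(base) - p)^2)))
#' @export
trilaterate4 <- function(base_coords, dists, tol = 1e-6, rel_tol = 1e-8) {
  base_coords <- as.matrix(base_coords)
  dists <- as.numeric(dists)
  if (nrow(base_coords) != 4L || length(dists) != 4L)
    stop_geobuild("geobuild_parse_error", "trilaterate4 needs 4 points and 4 distances")
  if (any(dists <= 0))
    stop_geobuild("geobuild_inconsistent_distances", "distances must be positive")
  if (is_degenerate(base_coords, rel_tol))
    stop_geobuild("geobuild_degenerate_base", "the four base points are coplanar")
  x1 <- base_coords[1, ]
  A <- 2 * (base_coords[2:4, , drop = FALSE] - matrix(x1, 3, 3, byrow = TRUE))
  sq <- rowSums(base_coords^2)
  b <- dists[1]^2 - dists[2:4]^2 + sq[2:4] - sq[1]
  p <- tryCatch(as.numeric(solve(A, b)), error = function(e)
    stop_geobuild("geobuild_degenerate_base",
                  "base is numerically singular (near-coplanar)"))
  res <- abs(sqrt(colSums((t(base_coords) - p)^2)) - dists)
  if (any(res > tol))
    stop_geobuild("geobuild_inconsistent_distances",
                  sprintf("trilateration residual %.3g exceeds tolerance %.3g",
                          max(res), tol))
  attr(p, "residuals") <- res
  p
}

#' Place a point from three positioned reference points (two candidates)
#'
#' Three spheres around non-collinear centres intersect in two points that
#' are mirror images across the plane of the centres (they coincide when the
#' target lies in that plane). The base is mapped to its canonical in-plane
#' frame, the in-plane coordinates are solved analytically, and both +z/-z
#' solutions are mapped back.
#'
#' @inheritParams trilaterate4
#' @param base_coords 3x3 matrix of reference coordinates.
#' @param dists length-3 distance vector.
#' @return Object of class `"placement_pair"`: list with `p_plus` and
#'   `p_minus`, both length-3 vectors satisfying the three distances.
#' @export
trilaterate3 <- function(base_coords, dists, tol = 1e-6, rel_tol = 1e-8) {
  base_coords <- as.matrix(base_coords)
  dists <- as.numeric(dists)
  if (nrow(base_coords) != 3L || length(dists) != 3L)
    stop_geobuild("geobuild_parse_error", "trilaterate3 needs 3 points and 3 distances")
  if (any(dists <= 0))
    stop_geobuild("geobuild_inconsistent_distances", "distances must be positive")
  if (is_degenerate(base_coords, rel_tol))
    stop_geobuild("geobuild_degenerate_base", "the three base points are collinear")
  p1 <- base_coords[1, ]
  v12 <- base_coords[2, ] - p1
  d12 <- sqrt(sum(v12^2))
  e1 <- v12 / d12
  u <- base_coords[3, ] - p1
  x3 <- sum(u * e1)
  e2 <- u - x3 * e1
  y3 <- sqrt(sum(e2^2))
  e2 <- e2 / y3
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  x <- (dists[1]^2 - dists[2]^2 + d12^2) / (2 * d12)
  y <- (dists[1]^2 - dists[3]^2 + x3^2 + y3^2 - 2 * x * x3) / (2 * y3)
  zsq <- dists[1]^2 - x^2 - y^2
  scale <- max(dists)^2
  if (zsq < -max(tol, 1e-12) * scale)
    stop_geobuild("geobuild_no_intersection",
                  "the three spheres do not intersect within tolerance")
  z <- sqrt(max(zsq, 0))
  inplane <- p1 + x * e1 + y * e2
  pair <- structure(list(p_plus = inplane + z * e3, p_minus = inplane - z * e3),
                    class = "placement_pair")
  # clamping a slightly negative zsq to 0 may leave residuals up to sqrt(-zsq)
  slack <- tol + sqrt(max(-zsq, 0))
  res <- vapply(pair, function(p)
    max(abs(sqrt(colSums((t(base_coords) - p)^2)) - dists)), numeric(1))
  if (max(res) > slack)
    stop_geobuild("geobuild_inconsistent_distances",
                  sprintf("trilateration residual %.3g exceeds tolerance %.3g",
                          max(res), slack))
  pair
}

#' Choose between the two mirror-image placement candidates
#'
#' Resolves the two-fold ambiguity of a 3-point placement using the known
#' distance to a fourth positioned atom that is not coplanar with the base:
#' the candidate whose distance to the reference atom better matches the
#' known distance is returned.
#'
#' @param candidates a `"placement_pair"` from [trilaterate3()].
#' @param ref_coord coordinate of the disambiguating atom.
#' @param ref_dist known distance from the unknown atom to the
#'   disambiguating atom.
#' @param tol tolerance in Angstrom: the chosen candidate's mismatch must be
#'   at most `tol`; if both candidates match within `tol` while being more
#'   than `tol` apart the reference is effectively coplanar and the
#'   placement is ambiguous.
#' @return The selected point (length-3 vector).
#' @export
disambiguate <- function(candidates, ref_coord, ref_dist, tol = 1e-6) {
  p_plus <- candidates$p_plus
  p_minus <- candidates$p_minus
  sep <- sqrt(sum((p_plus - p_minus)^2))
  if (sep <= tol) return(p_plus)
  e_plus <- abs(sqrt(sum((p_plus - ref_coord)^2)) - ref_dist)
  e_minus <- abs(sqrt(sum((p_minus - ref_coord)^2)) - ref_dist)
  if (e_plus <= tol && e_minus <= tol)
    stop_geobuild("geobuild_ambiguous_placement",
                  "both mirror candidates match the reference distance (near-coplanar reference)")
  if (min(e_plus, e_minus) > tol)
    stop_geobuild("geobuild_inconsistent_distances",
                  sprintf("neither candidate matches the reference distance (best %.3g > tol %.3g)",
                          min(e_plus, e_minus), tol))
  if (e_plus <= e_minus) p_plus else p_minus
}

#' Canonical local coordinates for a triangle from its three distances
#'
#' Fixes the local frame deterministically: atom 1 at the origin, atom 2 on
#' the +x axis, atom 3 in the xy-plane with `y >= 0`.
#'
#' @param d either a symmetric 3x3 distance matrix or the vector
#'   `c(d12, d13, d23)`.
#' @param rel_tol relative degeneracy tolerance.
#' @return 3x3 coordinate matrix reproducing the three distances.
#' @examples
#' init_triangle(c(3, 4, 5))  # third point at (0, 4, 0)
#' @export
init_triangle <- function(d, rel_tol = 1e-8) {
  if (is.matrix(d)) d <- c(d[1, 2], d[1, 3], d[2, 3])
  d <- as.numeric(d)
  if (length(d) != 3L || any(!is.finite(d)) || any(d <= 0))
    stop_geobuild("geobuild_parse_error", "init_triangle needs 3 positive distances")
  d12 <- d[1]; d13 <- d[2]; d23 <- d[3]
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3sq <- d13^2 - x3^2
  if (y3sq <= rel_tol * d13^2)
    stop_geobuild("geobuild_degenerate_base",
                  "triangle inequality violated or triangle degenerate")
  rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, sqrt(y3sq), 0))
}

#' Canonical local coordinates for a tetrahedron from its six distances
#'
#' Atom 1 at the origin, atom 2 on the +x axis, atom 3 in the xy-plane with
#' `y >= 0`, atom 4 with `z >= 0`. This fixed orientation convention makes
#' the output a deterministic function of the distances; the global
#' enantiomer it induces is resolved at evaluation time.
#'
#' @param d symmetric 4x4 distance matrix (only the upper triangle is read),
#'   or the length-6 vector `c(d12, d13, d14, d23, d24, d34)`.
#' @param rel_tol relative tolerance for the realizability and degeneracy
#'   tests: the squared height of atom 4 must be `>= -rel_tol * d14^2`
#'   (tiny negatives from roundoff are clamped to zero), and the resulting
#'   tetrahedron must pass [is_degenerate()].
#' @return 4x3 coordinate matrix reproducing all six distances.
#' @export
init_tetrahedron <- function(d, rel_tol = 1e-8) {
  if (is.matrix(d)) {
    dv <- c(d[1, 2], d[1, 3], d[1, 4], d[2, 3], d[2, 4], d[3, 4])
  } else dv <- as.numeric(d)
  if (length(dv) != 6L || any(!is.finite(dv)) || any(dv <= 0))
    stop_geobuild("geobuild_parse_error", "init_tetrahedron needs 6 positive distances")
  d12 <- dv[1]; d13 <- dv[2]; d14 <- dv[3]; d23 <- dv[4]; d24 <- dv[5]; d34 <- dv[6]
  tri <- init_triangle(c(d12, d13, d23), rel_tol)
  x3 <- tri[3, 1]; y3 <- tri[3, 2]
  x4 <- (d12^2 + d14^2 - d24^2) / (2 * d12)
  y4 <- (d14^2 - d34^2 + x3^2 + y3^2 - 2 * x4 * x3) / (2 * y3)
  z4sq <- d14^2 - x4^2 - y4^2
  if (z4sq < -rel_tol * d14^2)
    stop_geobuild("geobuild_not_realizable",
                  "the six distances are not realizable in 3D")
  out <- rbind(tri, c(x4, y4, sqrt(max(z4sq, 0))))
  if (is_degenerate(out, rel_tol))
    stop_geobuild("geobuild_degenerate_base",
                  "the six distances realize a flat (coplanar) tetrahedron")
  out
}
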