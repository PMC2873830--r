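# Evaluation of a reconstruction against its reference: aligned RMSD with
# optional reflection (exact distances cannot distinguish enantiomers, so
# the mirror image is an equally valid solution), and the largest violation
# of the input distances.

#' Aligned RMSD between two conformations
#'
#' Superposes `reconstructed` onto `reference` by centring both and applying
#' the optimal orthogonal map. With `allow_reflection = TRUE` (default) the
#' minimum is taken over proper rotations and roto-reflections — the
#' unconstrained Procrustes optimum — and `used_reflection` reports whether
#' the improper map was strictly better, i.e. which enantiomer was built.
#' With `allow_reflection = FALSE` the map is constrained to a proper
#' rotation (determinant +1).
#'
#' @param reconstructed,reference [structure3d()] objects (or bare `n x 3`
#'   matrices) with atoms in correspondence.
#' @param allow_reflection minimise over reflections too.
#' @param mask optional logical mask restricting the comparison (e.g. the
#'   positioned atoms of a partial reconstruction).
#' @return List with `rmsd` (Angstrom) and `used_reflection`.
#' @export
aligned_rmsd <- function(reconstructed, reference, allow_reflection = TRUE,
                         mask = NULL) {
  X <- if (inherits(reconstructed, "structure3d")) reconstructed$coords else as.matrix(reconstructed)
  Y <- if (inherits(reference, "structure3d")) reference$coords else as.matrix(reference)
  if (!is.null(mask)) {
    X <- X[mask, , drop = FALSE]
    Y <- Y[mask, , drop = FALSE]
  }
  if (nrow(X) != nrow(Y))
    stop_geobuild("geobuild_mismatched_atoms",
                  "structures differ in (positioned) atom count")
  if (anyNA(X) || anyNA(Y))
    stop_geobuild("geobuild_mismatched_atoms",
                  "NA coordinates in comparison; mask unpositioned atoms")
  cx <- center_points(Y)   # reference = target
  cy <- center_points(X)   # reconstructed = source
  C <- crossprod(cy$centered, cx$centered)
  s <- svd(C)
  Q_any <- s$u %*% t(s$v)                      # optimum over O(3)
  sgn <- sign(det(Q_any))
  Q_proper <- s$u %*% diag(c(1, 1, sgn)) %*% t(s$v)  # optimum over SO(3)
  r_any <- rmsd_points(cx$centered, cy$centered %*% Q_any)
  r_proper <- rmsd_points(cx$centered, cy$centered %*% Q_proper)
  if (allow_reflection && sgn < 0 && r_any < r_proper) {
    list(rmsd = r_any, used_reflection = TRUE)
  } else {
    list(rmsd = r_proper, used_reflection = FALSE)
  }
}

#' Largest violation of the input distances by a reconstruction
#'
#' The maximum over all input pairs with both endpoints positioned of the
#' absolute difference between the reconstructed inter-atomic distance and
#' the input distance.
#'
#' @param result a [reconstruction_result()].
#' @param dset the [sparse_distance_set()] that was solved.
#' @return Maximum absolute violation in Angstrom (`NA` if no pair has both
#'   endpoints positioned).
#' @export
max_distance_violation <- function(result, dset) {
  e <- dset$entries
  keep <- result$positioned[e$i] & result$positioned[e$j]
  if (!any(keep)) return(NA_real_)
  co <- result$structure$coords
  dd <- sqrt(rowSums((co[e$i[keep], , drop = FALSE] -
                        co[e$j[keep], , drop = FALSE])^2))
  max(abs(dd - e$d[keep]))
}

#' Run the reconstruction-and-evaluation protocol for several algorithms
#'
#' For each requested algorithm: build the cutoff distance set from the
#' reference coordinates (or use a supplied distance set), solve, and
#' evaluate. Solver failures become status rows, not errors.
#'
#' @param reference a [structure3d()] with the true coordinates, or `NULL`
#'   when starting from a bare distance set (then RMSD columns are `NA`).
#' @param dset optional [sparse_distance_set()]; built from `reference` at
#'   `cutoff` when missing.
#' @param cutoff cutoff in Angstrom (used only when `dset` is missing).
#' @param algorithms character vector among `"gb"`, `"ugb"`, `"rugb"`.
#' @param opts base [solver_options()]; its `algorithm` field is overridden
#'   per row.
#' @return Data frame with one row per algorithm: `algorithm`, `status`,
#'   `n_total`, `n_positioned`, `restart_count`, `aligned_rmsd`,
#'   `used_reflection`, `max_violation`.
#' @export
run_experiment <- function(reference = NULL, dset = NULL, cutoff = 5,
                           algorithms = c("gb", "ugb", "rugb"),
                           opts = solver_options()) {
  if (is.null(dset)) {
    if (is.null(reference))
      stop_geobuild("geobuild_parse_error", "need a reference or a distance set")
    dset <- build_distance_set(reference, cutoff)
  }
  rows <- lapply(algorithms, function(alg) {
    o <- opts
    o$algorithm <- alg
    res <- solve_buildup(dset, o)
    rmsd <- NA_real_; refl <- NA
    if (!is.null(reference) && res$status != "failed" && sum(res$positioned) >= 3) {
      ev <- aligned_rmsd(res$structure, reference, mask = res$positioned)
      rmsd <- ev$rmsd; refl <- ev$used_reflection
    }
    data.frame(algorithm = alg, status = res$status,
               n_total = dset$n, n_positioned = sum(res$positioned),
               restart_count = res$restart_count,
               aligned_rmsd = rmsd, used_reflection = refl,
               max_violation = if (res$status == "failed") NA_real_
                               else max_distance_violation(res, dset),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
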