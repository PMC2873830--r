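# The three build-up solvers. All share the same outer loop: seed four
# atoms from an initial 4-clique realized in a canonical frame, then sweep
# the unpositioned list in ascending id order, placing every atom for which
# a metric base can be found. They differ only in what counts as a base and
# in whether the base is re-initialized from original distances (updating):
#
#   gb   - any 4 positioned, non-coplanar neighbours; plain trilateration
#          against their current (error-accumulating) coordinates.
#   ugb  - 4 positioned neighbours whose 6 mutual distances are all in the
#          input set; the base is rebuilt exactly in a local frame, the new
#          atom solved there, and the K5 complex rigidly mapped back,
#          replacing the old base coordinates.
#   rugb - 3 positioned neighbours with their 3 mutual distances in the
#          input, plus one more positioned neighbour (not coplanar with the
#          triangle) whose distance to the new atom picks the correct mirror
#          image; base search walks only the atom's adjacency array.
#
# When a full sweep places nothing, the solver restarts from the next
# initial 4-clique (lexicographic enumeration), keeping the best partial.

#' Options controlling a build-up reconstruction
#'
#' @param algorithm `"gb"`, `"ugb"` or `"rugb"`.
#' @param degeneracy_rel_tol relative tolerance of the coplanarity /
#'   collinearity tests (see [is_degenerate()]).
#' @param distance_consistency_tol tolerance in Angstrom for trilateration
#'   residuals and mirror disambiguation on original-distance bases.
#' @param max_restarts maximum number of initial 4-cliques tried before
#'   returning the best partial result.
#' @param max_sweeps optional cap on sweeps per restart (default: no cap;
#'   each productive sweep places at least one atom so sweeps are bounded
#'   by the atom count anyway).
#' @param initial_base optional explicit 4 atom ids to seed from.
#' @return List of class `"solver_options"`.
#' @export
solver_options <- function(algorithm = c("rugb", "ugb", "gb"),
                           degeneracy_rel_tol = 1e-8,
                           distance_consistency_tol = 1e-6,
                           max_restarts = 25L,
                           max_sweeps = Inf,
                           initial_base = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(degeneracy_rel_tol > 0, distance_consistency_tol > 0,
            max_restarts >= 1)
  if (!is.null(initial_base)) {
    initial_base <- as.integer(initial_base)
    stopifnot(length(initial_base) == 4L, !anyDuplicated(initial_base))
  }
  structure(list(algorithm = algorithm,
                 degeneracy_rel_tol = degeneracy_rel_tol,
                 distance_consistency_tol = distance_consistency_tol,
                 max_restarts = as.integer(max_restarts),
                 max_sweeps = max_sweeps,
                 initial_base = initial_base),
            class = "solver_options")
}

#' Find an initial metric base (4-clique) in the distance graph
#'
#' Enumerates 4-cliques (four atoms with all six mutual distances known)
#' lexicographically by sorted id tuple and returns the first one, after
#' `skip` valid ones, whose distances realize a non-degenerate tetrahedron.
#' Successive `skip` values yield the distinct bases used by the restart
#' loop.
#'
#' @param idx an `"adjacency_index"`.
#' @param skip number of valid cliques to skip (restart counter).
#' @param rel_tol degeneracy tolerance.
#' @return Integer vector of 4 atom ids, or `NULL` when enumeration is
#'   exhausted after at least one valid clique was seen.
#'   Signals `geobuild_no_initial_base` when the graph has no valid
#'   4-clique at all.
#' @export
find_initial_base <- function(idx, skip = 0L, rel_tol = 1e-8) {
  n <- idx$n
  dmat <- idx$dmat
  seen <- 0L
  for (i in seq_len(n)) {
    nbi <- idx$neighbours[[i]]$id
    nbi <- nbi[nbi > i]
    if (length(nbi) < 3L) next
    for (ji in seq_along(nbi)) {
      j <- nbi[ji]
      for (ki in seq_along(nbi)) {
        if (ki <= ji) next
        k <- nbi[ki]
        if (dmat[j, k] <= 0) next
        for (li in seq_along(nbi)) {
          if (li <= ki) next
          l <- nbi[li]
          if (dmat[j, l] <= 0 || dmat[k, l] <= 0) next
          ids <- c(i, j, k, l)
          ok <- tryCatch({
            init_tetrahedron(dmat[ids, ids], rel_tol)
            TRUE
          }, geobuild_error = function(e) FALSE)
          if (ok) {
            if (seen >= skip) return(ids)
            seen <- seen + 1L
          }
        }
      }
    }
  }
  if (seen == 0L && skip == 0L)
    stop_geobuild("geobuild_no_initial_base",
                  "no non-degenerate 4-clique exists in the distance graph")
  NULL
}

# Enumerate 4-subsets of positioned neighbours that are non-coplanar at the
# current coordinates (GB base). Lexicographic order over the sorted
# neighbour ids; enumeration capped to bound pathological sweeps.
.gb_base_candidates <- function(atom, idx, positioned, coords, rel_tol,
                                require_mutual = FALSE, max_tests = 200L) {
  nbl <- idx$neighbours[[atom]]
  keep <- positioned[nbl$id]
  nb <- nbl$id[keep]
  m <- length(nb)
  if (m < 4L) return(NULL)
  dmat <- idx$dmat
  tests <- 0L
  out <- NULL
  for (a in 1:(m - 3L)) for (b in (a + 1L):(m - 2L)) {
    if (require_mutual && dmat[nb[a], nb[b]] <= 0) next
    for (cc in (b + 1L):(m - 1L)) {
      if (require_mutual &&
          (dmat[nb[a], nb[cc]] <= 0 || dmat[nb[b], nb[cc]] <= 0)) next
      for (dd in (cc + 1L):m) {
        if (require_mutual &&
            (dmat[nb[a], nb[dd]] <= 0 || dmat[nb[b], nb[dd]] <= 0 ||
             dmat[nb[cc], nb[dd]] <= 0)) next
        ids <- nb[c(a, b, cc, dd)]
        tests <- tests + 1L
        if (!is_degenerate(coords[ids, , drop = FALSE], rel_tol)) {
          out <- c(out, list(ids))
          if (length(out) >= 8L) return(out)
        }
        if (tests >= max_tests) return(out)
      }
    }
  }
  out
}

#' Find a 4-atom metric base for one unpositioned atom
#'
#' GB variant (`require_mutual = FALSE`): the first four positioned
#' neighbours of `atom` (lexicographic 4-subsets) whose current coordinates
#' are non-coplanar. UGB variant (`require_mutual = TRUE`): additionally all
#' six mutual distances among the four must be present in the original
#' distance set, so that the base can be re-initialized exactly.
#'
#' @param atom unpositioned atom id.
#' @param idx an `"adjacency_index"`.
#' @param positioned logical mask of currently positioned atoms.
#' @param coords current global coordinate matrix (rows of unpositioned
#'   atoms ignored).
#' @param require_mutual require original mutual distances (UGB).
#' @param rel_tol degeneracy tolerance.
#' @return A [metric_base()] or `NULL` if no base exists this sweep.
#' @export
find_base_4 <- function(atom, idx, positioned, coords, require_mutual = FALSE,
                        rel_tol = 1e-8) {
  cand <- .gb_base_candidates(atom, idx, positioned, coords, rel_tol,
                              require_mutual = require_mutual)
  if (is.null(cand) || length(cand) == 0L) return(NULL)
  metric_base(cand[[1L]], coords[cand[[1L]], , drop = FALSE])
}

# Enumerate RUGB (triangle, extra) candidates for one atom, walking only the
# atom's adjacency array. Returns list of list(tri=ids, extras=ids).
.rugb_base_candidates <- function(atom, idx, positioned, coords, rel_tol,
                                  max_triangles = 30L) {
  nbl <- idx$neighbours[[atom]]
  keep <- positioned[nbl$id]
  nb <- nbl$id[keep]
  m <- length(nb)
  if (m < 4L) return(NULL)
  dmat <- idx$dmat
  out <- list()
  tried <- 0L
  for (a in 1:(m - 2L)) for (b in (a + 1L):(m - 1L)) {
    if (dmat[nb[a], nb[b]] <= 0) next
    for (cc in (b + 1L):m) {
      if (dmat[nb[a], nb[cc]] <= 0 || dmat[nb[b], nb[cc]] <= 0) next
      tri <- nb[c(a, b, cc)]
      tried <- tried + 1L
      if (tried > max_triangles) return(out)
      # triangle must be realizable from original distances and
      # non-collinear at current coordinates
      ok <- tryCatch({
        init_triangle(c(dmat[tri[1], tri[2]], dmat[tri[1], tri[3]],
                        dmat[tri[2], tri[3]]), rel_tol)
        TRUE
      }, geobuild_error = function(e) FALSE)
      if (!ok || is_degenerate(coords[tri, , drop = FALSE], rel_tol)) next
      rest <- setdiff(nb, tri)
      extras <- rest[vapply(rest, function(e)
        !is_degenerate(coords[c(tri, e), , drop = FALSE], rel_tol),
        logical(1))]
      if (length(extras) > 0L)
        out <- c(out, list(list(tri = tri, extras = extras)))
      if (length(out) >= 8L) return(out)
    }
  }
  out
}

#' Find a 3-atom metric base plus disambiguating atom (RUGB)
#'
#' Searches only within the atom's adjacency array (length bounded by
#' `d_max`): first a positioned non-collinear triangle whose three mutual
#' distances are in the original set, then a positioned neighbour that is
#' not coplanar with the triangle. Triangles are enumerated lexicographically
#' over the sorted neighbour ids, extras in ascending id.
#'
#' @inheritParams find_base_4
#' @return A [metric_base()] with 3 base atoms and an `extra_id`, or `NULL`.
#' @export
find_base_3plus1 <- function(atom, idx, positioned, coords, rel_tol = 1e-8) {
  cand <- .rugb_base_candidates(atom, idx, positioned, coords, rel_tol)
  if (is.null(cand) || length(cand) == 0L) return(NULL)
  tri <- cand[[1L]]$tri
  extra <- cand[[1L]]$extras[1L]
  metric_base(tri, coords[tri, , drop = FALSE], extra_id = extra,
              extra_coord = coords[extra, ])
}

#' Place one atom by plain trilateration (GB step)
#'
#' @param base a 4-atom [metric_base()] carrying current global coordinates.
#' @param dists the atom's four original distances to the base atoms.
#' @param tol residual tolerance (GB runs with `Inf`: its base coordinates
#'   legitimately accumulate error).
#' @param rel_tol degeneracy tolerance.
#' @return The placed point (length-3 vector).
#' @export
place_atom_gb <- function(base, dists, tol = Inf, rel_tol = 1e-8) {
  trilaterate4(base$base_coords, dists, tol = tol, rel_tol = rel_tol)
}

#' Place one atom with a 4-atom updated base (UGB step)
#'
#' Rebuilds the base tetrahedron exactly from its six original distances in
#' a canonical local frame, solves the new atom there (all five atoms then
#' form a K5 complex whose ten distances are original), and rigidly maps the
#' five fresh atoms back onto the old base positions. The returned base
#' coordinates replace the old ones.
#'
#' @param base a 4-atom [metric_base()] (current global coordinates).
#' @param mutual_d symmetric 4x4 matrix of the base's original distances.
#' @param atom_d the atom's four original distances to the base atoms.
#' @param tol distance-consistency tolerance (Angstrom).
#' @param rel_tol degeneracy tolerance.
#' @return 5x3 matrix: updated global coordinates of the four base atoms
#'   (rows 1-4) and the newly placed atom (row 5).
#' @export
place_atom_ugb <- function(base, mutual_d, atom_d, tol = 1e-6, rel_tol = 1e-8) {
  local4 <- init_tetrahedron(mutual_d, rel_tol)
  local_atom <- trilaterate4(local4, atom_d, tol = tol, rel_tol = rel_tol)
  fresh <- rbind(local4, local_atom)
  reinsert(base$base_coords, fresh)
}

#' Place one atom with a 3-atom base plus disambiguating atom (RUGB step)
#'
#' Rebuilds the base triangle exactly from its three original distances,
#' solves the two mirror-image candidates in the local frame, rigidly maps
#' triangle and both candidates back onto the old triangle positions, and
#' picks the candidate whose distance to the disambiguating atom matches
#' the original distance.
#'
#' @param base a 3-atom [metric_base()] with `extra_id`/`extra_coord`.
#' @param mutual_d the triangle's three original distances
#'   `c(d12, d13, d23)` (or a symmetric 3x3 matrix).
#' @param atom_d the atom's three original distances to the triangle atoms.
#' @param extra_d the atom's original distance to the disambiguating atom.
#' @param tol distance-consistency tolerance (Angstrom).
#' @param rel_tol degeneracy tolerance.
#' @return 4x3 matrix: updated global coordinates of the three base atoms
#'   (rows 1-3) and the chosen position of the new atom (row 4).
#' @export
place_atom_rugb <- function(base, mutual_d, atom_d, extra_d, tol = 1e-6,
                            rel_tol = 1e-8) {
  local3 <- init_triangle(mutual_d, rel_tol)
  pair <- trilaterate3(local3, atom_d, tol = tol, rel_tol = rel_tol)
  fresh <- rbind(local3, pair$p_plus, pair$p_minus)
  mapped <- reinsert(base$base_coords, fresh)
  chosen <- disambiguate(
    structure(list(p_plus = mapped[4L, ], p_minus = mapped[5L, ]),
              class = "placement_pair"),
    base$extra_coord, extra_d, tol = tol)
  rbind(mapped[1:3, , drop = FALSE], chosen)
}

# One restart: seed from init_ids and sweep until complete or stalled.
.one_pass <- function(idx, init_ids, opts) {
  n <- idx$n
  dmat <- idx$dmat
  rel_tol <- opts$degeneracy_rel_tol
  tol <- opts$distance_consistency_tol
  coords <- matrix(NA_real_, n, 3L)
  positioned <- logical(n)
  coords[init_ids, ] <- init_tetrahedron(dmat[init_ids, init_ids], rel_tol)
  positioned[init_ids] <- TRUE
  prov <- list()
  sweep_no <- 0L
  repeat {
    sweep_no <- sweep_no + 1L
    placed <- 0L
    for (atom in which(!positioned)) {
      res <- switch(opts$algorithm,
        gb = .try_place_gb(atom, idx, positioned, coords, rel_tol),
        ugb = .try_place_ugb(atom, idx, positioned, coords, dmat, tol, rel_tol),
        rugb = .try_place_rugb(atom, idx, positioned, coords, dmat, tol, rel_tol))
      if (!is.null(res)) {
        coords[res$update_ids, ] <- res$update_coords
        coords[atom, ] <- res$atom_coord
        positioned[atom] <- TRUE
        placed <- placed + 1L
        prov[[length(prov) + 1L]] <-
          list(atom = atom, sweep = sweep_no, method = res$method,
               base = paste(res$base_ids, collapse = ","))
      }
    }
    if (all(positioned) || placed == 0L || sweep_no >= opts$max_sweeps) break
  }
  provenance <- if (length(prov)) {
    data.frame(atom = vapply(prov, `[[`, integer(1), "atom"),
               sweep = vapply(prov, `[[`, integer(1), "sweep"),
               method = vapply(prov, `[[`, character(1), "method"),
               base = vapply(prov, `[[`, character(1), "base"))
  } else {
    data.frame(atom = integer(0), sweep = integer(0),
               method = character(0), base = character(0))
  }
  list(coords = coords, positioned = positioned, provenance = provenance,
       complete = all(positioned))
}

.try_place_gb <- function(atom, idx, positioned, coords, rel_tol) {
  cand <- .gb_base_candidates(atom, idx, positioned, coords, rel_tol)
  for (ids in cand) {
    p <- tryCatch(
      trilaterate4(coords[ids, , drop = FALSE],
                   idx$dmat[ids, atom], tol = Inf, rel_tol = rel_tol),
      geobuild_error = function(e) NULL)
    if (!is.null(p))
      return(list(atom_coord = p, update_ids = integer(0),
                  update_coords = NULL, base_ids = ids, method = "gb"))
  }
  NULL
}

.try_place_ugb <- function(atom, idx, positioned, coords, dmat, tol, rel_tol) {
  cand <- .gb_base_candidates(atom, idx, positioned, coords, rel_tol,
                              require_mutual = TRUE, max_tests = 50L)
  for (ids in cand) {
    mb <- metric_base(ids, coords[ids, , drop = FALSE])
    upd <- tryCatch(
      place_atom_ugb(mb, dmat[ids, ids], dmat[ids, atom],
                     tol = tol, rel_tol = rel_tol),
      geobuild_error = function(e) NULL)
    if (!is.null(upd))
      return(list(atom_coord = upd[5L, ], update_ids = ids,
                  update_coords = upd[1:4, , drop = FALSE],
                  base_ids = ids, method = "ugb"))
  }
  # no all-original base: fall back to a plain (non-updated) placement
  fb <- .try_place_gb(atom, idx, positioned, coords, rel_tol)
  if (!is.null(fb)) fb$method <- "gb-fallback"
  fb
}

# geometric conditioning of a (triangle, extra) base: the product of the
# triangle's relative height (2*area / longest-edge^2) and the extra atom's
# relative off-plane distance. Flat triangles and near-coplanar extras make
# the rigid re-insertion ill-conditioned and amplify coordinate error (the
# "very flat tetrahedron" failure mode), so candidates are tried best-first.
.rugb_base_quality <- function(tri_coords, extra_coord) {
  v1 <- tri_coords[2, ] - tri_coords[1, ]
  v2 <- tri_coords[3, ] - tri_coords[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  a2 <- sqrt(sum(cr^2))                      # twice the area
  lmax2 <- max(sum(v1^2), sum(v2^2), sum((tri_coords[3, ] - tri_coords[2, ])^2))
  q_tri <- a2 / lmax2
  nrm <- cr / a2
  u <- extra_coord - colMeans(tri_coords)
  q_extra <- abs(sum(u * nrm)) / sqrt(sum(u^2))
  q_tri * q_extra
}

.try_place_rugb <- function(atom, idx, positioned, coords, dmat, tol, rel_tol) {
  cand <- .rugb_base_candidates(atom, idx, positioned, coords, rel_tol)
  if (length(cand) > 0L) {
    # expand to (triangle, extra) pairs scored by conditioning, best first
    flat <- list()
    for (cn in cand) for (extra in cn$extras)
      flat[[length(flat) + 1L]] <- list(
        tri = cn$tri, extra = extra,
        q = .rugb_base_quality(coords[cn$tri, , drop = FALSE], coords[extra, ]))
    cand <- flat[order(-vapply(flat, `[[`, numeric(1), "q"))]
  }
  for (cn in cand) {
    tri <- cn$tri
    for (extra in cn$extra) {
      mb <- metric_base(tri, coords[tri, , drop = FALSE],
                        extra_id = extra, extra_coord = coords[extra, ])
      upd <- tryCatch(
        place_atom_rugb(mb,
                        c(dmat[tri[1], tri[2]], dmat[tri[1], tri[3]],
                          dmat[tri[2], tri[3]]),
                        dmat[tri, atom], dmat[extra, atom],
                        tol = tol, rel_tol = rel_tol),
        geobuild_error = function(e) NULL)
      if (!is.null(upd))
        return(list(atom_coord = upd[4L, ], update_ids = tri,
                    update_coords = upd[1:3, , drop = FALSE],
                    base_ids = c(tri, extra), method = "rugb"))
    }
  }
  fb <- .try_place_gb(atom, idx, positioned, coords, rel_tol)
  if (!is.null(fb)) fb$method <- "gb-fallback"
  fb
}

#' Reconstruct a structure from a sparse set of exact distances
#'
#' Runs the selected build-up algorithm: seeds four atoms from an initial
#' 4-clique realized in a canonical frame, sweeps the unpositioned atom list
#' in ascending id order placing every atom with a valid metric base, and on
#' a stalled sweep restarts from the next initial 4-clique (up to
#' `max_restarts`), returning the best result found.
#'
#' The reconstructed coordinates are determined up to a rigid motion and
#' possibly a reflection of the true structure; use [aligned_rmsd()] to
#' compare against a reference.
#'
#' @param dset a [sparse_distance_set()] with at least 4 atoms.
#' @param opts a [solver_options()].
#' @return A [reconstruction_result()].
#' @examples
#' s <- generate_structure(generator_config(n = 30, mode = "cloud", seed = 1))
#' dset <- build_distance_set(s, Inf)
#' res <- solve_buildup(dset, solver_options("rugb"))
#' aligned_rmsd(res$structure, s)$rmsd
#' @export
solve_buildup <- function(dset, opts = solver_options()) {
  if (dset$n < 4L)
    stop_geobuild("geobuild_parse_error", "need at least 4 atoms")
  idx <- build_adjacency_index(dset)
  best <- NULL
  restarts <- 0L
  empty_prov <- data.frame(atom = integer(0), sweep = integer(0),
                           method = character(0), base = character(0))
  for (r in seq_len(opts$max_restarts) - 1L) {
    if (!is.null(opts$initial_base) && r == 0L) {
      init_ids <- opts$initial_base
    } else {
      skip <- if (is.null(opts$initial_base)) r else r - 1L
      init_ids <- tryCatch(
        find_initial_base(idx, skip = skip, rel_tol = opts$degeneracy_rel_tol),
        geobuild_no_initial_base = function(e) NULL)
    }
    if (is.null(init_ids)) break  # no clique at all, or enumeration exhausted
    restarts <- restarts + 1L
    pass <- .one_pass(idx, init_ids, opts)
    if (is.null(best) || sum(pass$positioned) > sum(best$positioned))
      best <- pass
    if (pass$complete) break
  }
  if (is.null(best))
    return(reconstruction_result(.structure3d_na(dset$n), logical(dset$n),
                                 "failed", empty_prov, restarts))
  st <- .structure3d_na(dset$n)
  st$coords[] <- best$coords
  status <- if (best$complete) "complete" else "partial"
  reconstruction_result(st, best$positioned, status, best$provenance, restarts)
}

# structure3d shell that tolerates NA rows for unpositioned atoms
.structure3d_na <- function(n) {
  structure(list(coords = matrix(NA_real_, n, 3L), labels = NULL),
            class = "structure3d")
}
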