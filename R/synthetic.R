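# Synthetic ground-truth structures with solvable cutoff graphs, so the
# solvers can be exercised end-to-end without external coordinate files.
# Chain mode emulates a polypeptide trace at protein-like packing density;
# cloud mode is an unstructured point set at the same density.

# run code under a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic structure generator
#'
#' Defaults emulate protein-like geometry: a 1.5 Angstrom bond length
#' (roughly a C-C bond along a backbone trace), a 1.0 Angstrom excluded
#' volume between non-bonded atoms, a packing density of 0.05 atoms per
#' cubic Angstrom (typical for protein interiors), and a 5 Angstrom cutoff
#' for the observable distances (the NMR-style regime).
#'
#' @param n atom count (at least 5).
#' @param mode `"chain"` (self-avoiding confined random walk with fixed bond
#'   length) or `"cloud"` (uniform points with minimum separation).
#' @param bond_length chain bond length, Angstrom.
#' @param min_separation minimum non-bonded inter-atomic distance, Angstrom.
#' @param density target packing density, atoms per cubic Angstrom; sets the
#'   confining sphere (chain) or cube (cloud) size.
#' @param cutoff distance cutoff for [generate_solvable_instance()], Angstrom.
#' @param angle_jitter chain direction persistence: standard deviation of
#'   the Gaussian perturbation added to the previous bond direction before
#'   renormalising (dimensionless; larger = floppier chain).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n, mode = c("chain", "cloud"), bond_length = 1.5,
                             min_separation = 1.0, density = 0.05,
                             cutoff = 5, angle_jitter = 0.7, seed = NULL) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  stopifnot(n >= 5L, bond_length > 0, min_separation > 0, density > 0,
            cutoff > min_separation)
  structure(list(n = n, mode = mode, bond_length = bond_length,
                 min_separation = min_separation, density = density,
                 cutoff = cutoff, angle_jitter = angle_jitter, seed = seed),
            class = "generator_config")
}

.unit <- function(v) v / sqrt(sum(v^2))

.gen_chain <- function(cfg) {
  n <- cfg$n
  R <- (3 * n / (4 * pi * cfg$density))^(1 / 3)
  for (restart in 1:25) {
    pos <- matrix(NA_real_, n, 3L)
    pos[1L, ] <- c(0, 0, 0)
    dir <- .unit(stats::rnorm(3))
    ok <- TRUE
    for (k in 2:n) {
      placed <- FALSE
      for (try in 1:200) {
        nd <- .unit(dir + cfg$angle_jitter * stats::rnorm(3))
        cand <- pos[k - 1L, ] + cfg$bond_length * nd
        if (sum(cand^2) > R^2) next
        if (k > 2L) {
          prev <- pos[1:(k - 2L), , drop = FALSE]
          if (min(rowSums((prev - matrix(cand, k - 2L, 3L, byrow = TRUE))^2)) <
              cfg$min_separation^2) next
        }
        pos[k, ] <- cand
        dir <- nd
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  stop_geobuild("geobuild_generation_failure",
                "chain generator exhausted its retry budget")
}

.gen_cloud <- function(cfg) {
  n <- cfg$n
  L <- (n / cfg$density)^(1 / 3)
  pos <- matrix(NA_real_, n, 3L)
  placed <- 0L
  for (it in seq_len(400L * n)) {
    cand <- stats::runif(3, 0, L)
    if (placed > 0L) {
      prev <- pos[1:placed, , drop = FALSE]
      if (min(rowSums((prev - matrix(cand, placed, 3L, byrow = TRUE))^2)) <
          cfg$min_separation^2) next
    }
    placed <- placed + 1L
    pos[placed, ] <- cand
    if (placed == n) return(pos)
  }
  stop_geobuild("geobuild_generation_failure",
                "cloud generator exhausted its retry budget")
}

#' Generate a synthetic ground-truth structure
#'
#' @param cfg a [generator_config()].
#' @return A [structure3d()]; deterministic for a given `cfg$seed`.
#' @examples
#' s <- generate_structure(generator_config(n = 50, seed = 7))
#' @export
generate_structure <- function(cfg) {
  pos <- with_seed(cfg$seed, switch(cfg$mode,
                                    chain = .gen_chain(cfg),
                                    cloud = .gen_cloud(cfg)))
  structure3d(pos)
}

# Combinatorial dry run of the RUGB base-existence check: can a build-up
# ordering position every atom, looking only at the graph (no coordinates)?
.rugb_reachable <- function(dset) {
  idx <- build_adjacency_index(dset)
  n <- idx$n
  init <- tryCatch(find_initial_base(idx, skip = 0L),
                   geobuild_no_initial_base = function(e) NULL)
  if (is.null(init)) return(FALSE)
  dmat <- idx$dmat
  positioned <- logical(n)
  positioned[init] <- TRUE
  repeat {
    placed <- 0L
    for (atom in which(!positioned)) {
      nb <- idx$neighbours[[atom]]$id
      nb <- nb[positioned[nb]]
      m <- length(nb)
      if (m < 4L) next
      found <- FALSE
      for (a in 1:(m - 2L)) {
        for (b in (a + 1L):(m - 1L)) {
          if (dmat[nb[a], nb[b]] <= 0) next
          for (cc in (b + 1L):m) {
            if (dmat[nb[a], nb[cc]] > 0 && dmat[nb[b], nb[cc]] > 0) {
              found <- TRUE; break
            }
          }
          if (found) break
        }
        if (found) break
      }
      if (found) { positioned[atom] <- TRUE; placed <- placed + 1L }
    }
    if (all(positioned)) return(TRUE)
    if (placed == 0L) return(FALSE)
  }
}

#' Generate a structure together with a solvable sparse distance set
#'
#' Builds the cutoff distance set of a generated structure and verifies, by
#' a purely combinatorial dry run of the RUGB base-existence check (graph
#' search only, no coordinates), that a build-up ordering positioning every
#' atom exists. If not, the cutoff is increased by 10% and the check is
#' retried (bounded). Geometric degeneracies are left to the solvers and
#' surface as restarts.
#'
#' @param cfg a [generator_config()].
#' @return List with `structure`, `dset`, and `cutoff` (the cutoff actually
#'   used, possibly larger than requested).
#' @export
generate_solvable_instance <- function(cfg) {
  s <- generate_structure(cfg)
  cutoff <- cfg$cutoff
  for (attempt in 1:6) {
    dset <- build_distance_set(s, cutoff)
    if (.rugb_reachable(dset))
      return(list(structure = s, dset = dset, cutoff = cutoff))
    cutoff <- cutoff * 1.1
  }
  stop_geobuild("geobuild_generation_failure",
                "no solvable instance found within the cutoff retry budget")
}

#' Add isotropic Gaussian noise to coordinates
#'
#' Used to probe error propagation: the updating step of UGB/RUGB should
#' keep placements exact even when previously positioned coordinates carry
#' noise.
#'
#' @param structure a [structure3d()].
#' @param sigma per-coordinate standard deviation, Angstrom.
#' @param seed integer seed.
#' @return A new [structure3d()].
#' @export
perturb_coordinates <- function(structure, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  co <- structure$coords
  noise <- with_seed(seed, matrix(stats::rnorm(length(co), 0, sigma), nrow(co), 3L))
  structure3d(co + noise, labels = structure$labels)
}
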