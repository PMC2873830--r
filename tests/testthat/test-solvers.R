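test_that("find_initial_base returns the first valid 4-clique deterministically", {
  withr::with_seed(51, {
    s <- generate_structure(generator_config(n = 10, mode = "cloud", seed = 51))
    dset <- build_distance_set(s, Inf)
    idx <- build_adjacency_index(dset)
    base <- find_initial_base(idx)
    expect_equal(base, 1:4)
    # restart enumeration yields a distinct base
    base2 <- find_initial_base(idx, skip = 1L)
    expect_false(identical(base, base2))
    # postcondition: all six mutual distances present
    for (a in 1:3) for (b in (a + 1):4)
      expect_false(is.na(has_distance(idx, base[a], base[b])))
  })
})

test_that("a path graph has no initial base and the solver reports failure", {
  n <- 6
  dset <- sparse_distance_set(1:(n - 1), 2:n, rep(1.5, n - 1), n = n)
  idx <- build_adjacency_index(dset)
  expect_error(find_initial_base(idx), class = "geobuild_no_initial_base")
  res <- solve_buildup(dset, solver_options("rugb"))
  expect_equal(res$status, "failed")
  expect_equal(sum(res$positioned), 0L)
})

test_that("find_base_4 picks positioned non-coplanar neighbours", {
  withr::with_seed(53, {
    # atom 5 with exactly 4 positioned non-coplanar neighbours
    coords <- rbind(unit_tetrahedron(), c(0.4, 0.3, 0.2))
    dset <- build_distance_set(structure3d(coords), Inf)
    idx <- build_adjacency_index(dset)
    positioned <- c(rep(TRUE, 4), FALSE)
    mb <- find_base_4(5, idx, positioned, coords)
    expect_equal(mb$base_ids, 1:4)
    # only 3 positioned neighbours: no base
    expect_null(find_base_4(5, idx, c(TRUE, TRUE, TRUE, FALSE, FALSE), coords))
    # 5 positioned neighbours, exactly one non-coplanar 4-subset:
    # four coplanar points plus one off-plane point
    coords2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                     c(0.5, 0.5, 1), c(0.5, 0.2, 0.4))
    dset2 <- build_distance_set(structure3d(coords2), Inf)
    idx2 <- build_adjacency_index(dset2)
    mb2 <- find_base_4(6, idx2, c(rep(TRUE, 5), FALSE), coords2)
    # oracle: enumerate all C(5,4) subsets, keep the non-coplanar ones
    subs <- utils::combn(5, 4)
    ok <- which(!apply(subs, 2, function(s)
      is_degenerate(coords2[s, , drop = FALSE])))
    expect_length(ok, 4L)  # every subset containing atom 5 works
    expect_equal(mb2$base_ids, subs[, ok[1]])
  })
})

test_that("find_base_3plus1 matches exhaustive search over the neighbour array", {
  # unit triangle plus an apex: base = triangle, extra = apex
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                  c(0.5, sqrt(3) / 6, sqrt(6) / 3), c(0.5, 0.3, -0.8))
  dset <- build_distance_set(structure3d(coords), Inf)
  idx <- build_adjacency_index(dset)
  mb <- find_base_3plus1(5, idx, c(rep(TRUE, 4), FALSE), coords)
  expect_equal(mb$base_ids, 1:3)
  expect_equal(mb$extra_id, 4L)
  # all positioned neighbours coplanar: no valid extra
  coords_flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                       c(0.5, 0.5, 0.7))
  dsetf <- build_distance_set(structure3d(coords_flat), Inf)
  idxf <- build_adjacency_index(dsetf)
  expect_null(find_base_3plus1(5, idxf, c(rep(TRUE, 4), FALSE), coords_flat))
  # seeded sparse instance: first-candidate output equals brute force over
  # the atom's neighbour array only
  withr::with_seed(59, {
    inst <- generate_solvable_instance(
      generator_config(n = 60, mode = "chain", cutoff = 5, seed = 59))
    idx2 <- build_adjacency_index(inst$dset)
    coords2 <- inst$structure$coords
    positioned <- rep(TRUE, 60)
    for (atom in sample(60, 8)) {
      positioned_a <- positioned; positioned_a[atom] <- FALSE
      mb2 <- find_base_3plus1(atom, idx2, positioned_a, coords2)
      # brute force: lexicographic triples of positioned neighbours with all
      # mutual distances, then ascending extras non-coplanar with the triple
      nb <- idx2$neighbours[[atom]]$id
      nb <- nb[positioned_a[nb]]
      oracle <- NULL
      m <- length(nb)
      if (m >= 4) {
        for (a in 1:(m - 2)) { for (b in (a + 1):(m - 1)) { for (cc in (b + 1):m) {
          tri <- nb[c(a, b, cc)]
          if (is.na(has_distance(idx2, tri[1], tri[2])) ||
              is.na(has_distance(idx2, tri[1], tri[3])) ||
              is.na(has_distance(idx2, tri[2], tri[3]))) next
          if (is_degenerate(coords2[tri, , drop = FALSE])) next
          extras <- setdiff(nb, tri)
          extras <- extras[!vapply(extras, function(e)
            is_degenerate(coords2[c(tri, e), , drop = FALSE]), logical(1))]
          if (length(extras)) { oracle <- list(tri = tri, extra = extras[1]); break }
        }; if (!is.null(oracle)) break }; if (!is.null(oracle)) break }
      }
      if (is.null(oracle)) {
        expect_null(mb2)
      } else {
        expect_equal(mb2$base_ids, oracle$tri)
        expect_equal(mb2$extra_id, oracle$extra)
      }
    }
  })
})

test_that("the UGB updating step repairs noisy base coordinates", {
  withr::with_seed(61, {
    tet <- unit_tetrahedron() * 2.5
    target <- c(1.2, 0.8, 0.5)
    dm <- as.matrix(dist(rbind(tet, target)))
    noisy <- tet + matrix(rnorm(12, 0, 1e-6), 4, 3)
    mb <- metric_base(1:4, noisy)
    upd <- place_atom_ugb(mb, dm[1:4, 1:4], dm[5, 1:4])
    # the K5 complex reproduces all original distances even though the old
    # base carried 1e-6 noise
    expect_coords_equal(as.matrix(dist(upd)), dm, tol = 1e-9)
    # idempotence on exact input
    mb_exact <- metric_base(1:4, tet)
    upd2 <- place_atom_ugb(mb_exact, dm[1:4, 1:4], dm[5, 1:4])
    expect_coords_equal(upd2[1:4, ], tet, tol = 1e-10)
    expect_coords_equal(sqrt(colSums((t(upd2[1:4, ]) - upd2[5, ])^2)),
                        dm[5, 1:4], tol = 1e-10)
  })
})

test_that("the RUGB updating step places exactly and rejects the mirror trap", {
  tri <- init_triangle(c(1, 1, 1))
  apex <- c(0.5, sqrt(3) / 6, sqrt(6) / 3)
  target <- c(0.5, 0.1, -0.6)
  all5 <- rbind(tri, apex, target)
  dm <- as.matrix(dist(all5))
  mb <- metric_base(1:3, tri, extra_id = 4L, extra_coord = apex)
  upd <- place_atom_rugb(mb, dm[1:3, 1:3][upper.tri(dm[1:3, 1:3])][c(1, 2, 3)],
                         dm[5, 1:3], dm[5, 4])
  expect_coords_equal(upd[4, ], target, tol = 1e-10)
  expect_coords_equal(sqrt(colSums((t(upd[1:3, ]) - upd[4, ])^2)),
                      dm[5, 1:3], tol = 1e-10)
  # coplanar extra atom cannot break the mirror symmetry
  flat_extra <- c(2, 2, 0)
  mbf <- metric_base(1:3, tri, extra_id = 4L, extra_coord = flat_extra)
  expect_error(
    place_atom_rugb(mbf, c(1, 1, 1), dm[5, 1:3],
                    sqrt(sum((target - flat_extra)^2))),
    class = "geobuild_ambiguous_placement")
})

test_that("RUGB and UGB placements agree after noise repair", {
  withr::with_seed(67, {
    tet <- unit_tetrahedron() * 3
    target <- c(1.4, 0.9, 0.7)
    dm <- as.matrix(dist(rbind(tet, target)))
    noisy <- tet + matrix(rnorm(12, 0, 1e-7), 4, 3)
    upd_ugb <- place_atom_ugb(metric_base(1:4, noisy), dm[1:4, 1:4], dm[5, 1:4])
    mb3 <- metric_base(1:3, noisy[1:3, ], extra_id = 4L, extra_coord = noisy[4, ])
    upd_rugb <- place_atom_rugb(mb3, c(dm[1, 2], dm[1, 3], dm[2, 3]),
                                dm[5, 1:3], dm[5, 4])
    expect_lt(sqrt(sum((upd_ugb[5, ] - upd_rugb[4, ])^2)), 1e-6)
  })
})

test_that("all three solvers are exact on a complete-distance cloud", {
  s <- generate_structure(generator_config(n = 50, mode = "cloud", seed = 71))
  dset <- build_distance_set(s, Inf)
  for (alg in c("gb", "ugb", "rugb")) {
    res <- solve_buildup(dset, solver_options(alg))
    expect_equal(res$status, "complete")
    expect_lt(aligned_rmsd(res$structure, s)$rmsd, 1e-8)
  }
})

test_that("RUGB completes a sparse synthetic chain with tiny error", {
  inst <- generate_solvable_instance(
    generator_config(n = 150, mode = "chain", cutoff = 5, seed = 73))
  res <- solve_buildup(inst$dset, solver_options("rugb"))
  expect_equal(res$status, "complete")
  expect_lt(aligned_rmsd(res$structure, inst$structure)$rmsd, 1e-6)
})

test_that("distance consistency holds for UGB and RUGB on sparse exact data", {
  inst <- generate_solvable_instance(
    generator_config(n = 120, mode = "chain", cutoff = 5, seed = 79))
  for (alg in c("ugb", "rugb")) {
    res <- solve_buildup(inst$dset, solver_options(alg))
    expect_equal(res$status, "complete")
    expect_lt(max_distance_violation(res, inst$dset), 1e-6)
  }
})

test_that("every atom beyond the initial base has provenance; sweeps make progress", {
  inst <- generate_solvable_instance(
    generator_config(n = 80, mode = "chain", cutoff = 5, seed = 83))
  res <- solve_buildup(inst$dset, solver_options("rugb"))
  expect_equal(res$status, "complete")
  expect_equal(nrow(res$provenance), 80L - 4L)
  init_ids <- find_initial_base(build_adjacency_index(inst$dset))
  expect_setequal(res$provenance$atom, setdiff(1:80, init_ids))
  # each sweep that ran placed at least one atom
  counts <- table(res$provenance$sweep)
  expect_true(all(counts >= 1))
  expect_equal(sort(unique(res$provenance$sweep)), seq_along(counts))
})

test_that("an explicit initial base is honoured", {
  s <- generate_structure(generator_config(n = 20, mode = "cloud", seed = 89))
  dset <- build_distance_set(s, Inf)
  res <- solve_buildup(dset, solver_options("ugb", initial_base = c(5, 6, 7, 8)))
  expect_equal(res$status, "complete")
  expect_false(any(res$provenance$atom %in% 5:8))
})
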