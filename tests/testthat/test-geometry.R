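test_that("trilaterate4 recovers the circumcentre of the regular tetrahedron", {
  tet <- unit_tetrahedron()
  p <- trilaterate4(tet, rep(sqrt(6) / 4, 4))
  # verify by direct computation: equidistant from all four vertices
  expect_coords_equal(sqrt(colSums((t(tet) - as.numeric(p))^2)),
                      rep(sqrt(6) / 4, 4), tol = 1e-12)
  expect_coords_equal(as.numeric(p), c(0.5, sqrt(3) / 6, sqrt(6) / 12), tol = 1e-12)
})

test_that("trilaterate4 returns the generating point on exact instances", {
  withr::with_seed(42, {
    for (k in 1:25) {
      inst <- random_trilat4_instance()
      p <- trilaterate4(inst$base, inst$dists)
      expect_coords_equal(as.numeric(p), inst$p, tol = 1e-9)
    }
  })
})

test_that("trilaterate4 rejects degenerate bases and corrupted distances", {
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(trilaterate4(flat, rep(1, 4)), class = "geobuild_degenerate_base")
  tet <- unit_tetrahedron()
  expect_error(trilaterate4(tet, c(1, 1, 1, 3)),  # inconsistent 4th distance
               class = "geobuild_inconsistent_distances")
})

test_that("trilaterate3 yields both apexes of the regular tetrahedron", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  pair <- trilaterate3(tri, rep(1, 3))
  expect_coords_equal(pair$p_plus, c(0.5, sqrt(3) / 6, sqrt(6) / 3), tol = 1e-12)
  expect_coords_equal(pair$p_minus, c(0.5, sqrt(3) / 6, -sqrt(6) / 3), tol = 1e-12)
  for (p in pair)
    expect_coords_equal(sqrt(colSums((t(tri) - p)^2)), rep(1, 3), tol = 1e-12)
})

test_that("an in-plane target gives coincident candidates", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  target <- c(0.5, 0.2, 0)
  pair <- trilaterate3(tri, sqrt(colSums((t(tri) - target)^2)))
  # the out-of-plane component is sqrt of a roundoff-level quantity, so the
  # candidates coincide only to ~sqrt(eps)
  expect_coords_equal(pair$p_plus, target, tol = 1e-6)
  expect_coords_equal(pair$p_minus, target, tol = 1e-6)
  expect_lt(sqrt(sum((pair$p_plus - pair$p_minus)^2)), 1e-6)
})

test_that("trilaterate3 candidates are exact mirror images across the base plane", {
  withr::with_seed(7, {
    for (k in 1:50) {
      inst <- random_trilat3_instance()
      pair <- trilaterate3(inst$base, inst$dists)
      mid <- (pair$p_plus + pair$p_minus) / 2
      dif <- pair$p_plus - pair$p_minus
      v1 <- inst$base[2, ] - inst$base[1, ]
      v2 <- inst$base[3, ] - inst$base[1, ]
      nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
               v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      # midpoint in the base plane
      expect_lt(abs(sum((mid - inst$base[1, ]) * nrm)) /
                  max(1, sqrt(sum(mid^2))), 1e-9)
      # difference parallel to the normal
      expect_lt(sqrt(sum((dif - sum(dif * nrm) * nrm)^2)) /
                  max(1, sqrt(sum(dif^2))), 1e-9)
      # one candidate is the generating point
      err <- min(sqrt(sum((pair$p_plus - inst$p)^2)),
                 sqrt(sum((pair$p_minus - inst$p)^2)))
      expect_lt(err, 1e-9)
    }
  })
})

test_that("trilaterate3 rejects collinear bases and non-intersecting spheres", {
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(trilaterate3(line, rep(1, 3)), class = "geobuild_degenerate_base")
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_error(trilaterate3(tri, c(0.1, 0.1, 5)),
               class = "geobuild_no_intersection")
})

test_that("disambiguate picks the candidate matching the reference distance", {
  plus <- c(0.5, sqrt(3) / 6, sqrt(6) / 3)
  minus <- c(0.5, sqrt(3) / 6, -sqrt(6) / 3)
  pair <- structure(list(p_plus = plus, p_minus = minus), class = "placement_pair")
  ref <- c(0, 0, 2)
  expect_coords_equal(disambiguate(pair, ref, sqrt(sum((plus - ref)^2))), plus,
                      tol = 1e-12)
  expect_coords_equal(disambiguate(pair, ref, sqrt(sum((minus - ref)^2))), minus,
                      tol = 1e-12)
  # coplanar reference: both candidates equidistant -> ambiguous
  expect_error(disambiguate(pair, c(5, 5, 0), sqrt(sum((plus - c(5, 5, 0))^2))),
               class = "geobuild_ambiguous_placement")
  # neither matches
  expect_error(disambiguate(pair, ref, 10),
               class = "geobuild_inconsistent_distances")
  # coincident candidates are returned regardless of the reference
  co <- structure(list(p_plus = plus, p_minus = plus), class = "placement_pair")
  expect_identical(disambiguate(co, ref, 99), plus)
})

test_that("seeded random disambiguation matches exhaustive candidate check", {
  withr::with_seed(13, {
    for (k in 1:50) {
      inst <- random_trilat3_instance()
      pair <- trilaterate3(inst$base, inst$dists)
      # reference: a random point off the plane with exact distance to inst$p
      ref <- inst$p + stats::runif(3, -4, 4)
      truth <- if (sqrt(sum((pair$p_plus - inst$p)^2)) <
                   sqrt(sum((pair$p_minus - inst$p)^2))) pair$p_plus else pair$p_minus
      got <- tryCatch(
        disambiguate(pair, ref, sqrt(sum((inst$p - ref)^2))),
        geobuild_ambiguous_placement = function(e) NULL)
      if (!is.null(got)) expect_coords_equal(got, truth, tol = 1e-9)
    }
  })
})

test_that("init_triangle fixes the canonical frame", {
  expect_coords_equal(init_triangle(c(1, 1, 1)),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                      tol = 1e-12)
  expect_coords_equal(init_triangle(c(3, 4, 5)),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), tol = 1e-12)
  expect_error(init_triangle(c(1, 2, 3)), class = "geobuild_degenerate_base")
})

test_that("init_tetrahedron reproduces its distances with the fixed orientation", {
  out <- init_tetrahedron(rep(1, 6))
  expect_coords_equal(out, unit_tetrahedron(), tol = 1e-12)
  # axis-aligned right tetrahedron: output congruent to the generating points
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  dm <- as.matrix(dist(pts))
  out2 <- init_tetrahedron(dm)
  expect_lt(aligned_rmsd(out2, pts)$rmsd, 1e-10)
  expect_coords_equal(as.matrix(dist(out2)), dm, tol = 1e-9)
  expect_true(out2[3, 2] >= 0 && out2[4, 3] >= 0)
  # four collinear points
  pts_flat <- cbind(0:3, 0, 0)
  expect_error(init_tetrahedron(as.matrix(dist(pts_flat))),
               class = "geobuild_error")
})

test_that("local initialization is bit-deterministic across calls", {
  pts <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(0.4, 1.1, 0), c(0.7, 0.3, 0.9))
  dm <- as.matrix(dist(pts))
  expect_identical(init_tetrahedron(dm), init_tetrahedron(dm))
  expect_identical(init_triangle(dm[1:3, 1:3]), init_triangle(dm[1:3, 1:3]))
})

test_that("is_degenerate applies the scaled determinant test", {
  expect_false(is_degenerate(unit_tetrahedron()))
  expect_true(is_degenerate(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 3, 0))))
  near_flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                     c(0.5, sqrt(3) / 6, 1e-12))
  expect_true(is_degenerate(near_flat, rel_tol = 1e-8))
  expect_false(is_degenerate(near_flat, rel_tol = 1e-14))
  expect_true(is_degenerate(rbind(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3))))
})
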