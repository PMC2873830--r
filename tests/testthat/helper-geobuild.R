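# Shared fixtures and independent oracles, built in code.

# Multi-start nonlinear least-squares placement oracle: minimises
# sum over i of (||x - x_i|| - d_i)^2 by BFGS from several starts and
# returns the best minimiser. Independent of the closed-form trilateration
# it is used to check.
nls_placement_oracle <- function(base_coords, dists, n_starts = 4) {
  obj <- function(x) {
    r <- sqrt(colSums((t(base_coords) - x)^2)) - dists
    sum(r^2)
  }
  grad <- function(x) {
    dif <- matrix(x, nrow(base_coords), 3, byrow = TRUE) - base_coords
    nr <- sqrt(rowSums(dif^2))
    colSums(2 * (nr - dists) / nr * dif)
  }
  polish <- function(x) {  # Gauss-Newton to machine precision
    for (it in 1:30) {
      dif <- matrix(x, nrow(base_coords), 3, byrow = TRUE) - base_coords
      nr <- pmax(sqrt(rowSums(dif^2)), 1e-12)
      J <- dif / nr
      r <- nr - dists
      dx <- tryCatch(solve(crossprod(J) + 1e-14 * diag(3), -crossprod(J, r)),
                     error = function(e) NULL)
      if (is.null(dx)) break
      x <- x + as.numeric(dx)
      if (sqrt(sum(dx^2)) < 1e-14) break
    }
    x
  }
  ctr <- colMeans(base_coords)
  scale <- max(dists)
  starts <- rbind(ctr, ctr + c(1, 1, 1), ctr + c(-1, 2, -0.5), ctr + c(0.5, -1, 2))
  best <- NULL
  k <- 0L
  # exact distances guarantee a zero-residual global minimum; restart from
  # random seeds (deterministic stream) until it is reached
  while (k < max(n_starts, 60L)) {
    k <- k + 1L
    st <- if (k <= nrow(starts)) starts[k, ] else ctr + stats::rnorm(3, 0, scale)
    fit <- stats::optim(st, obj, grad, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 500))
    x <- polish(fit$par)
    v <- obj(x)
    if (is.null(best) || v < best$v) best <- list(x = x, v = v)
    if (best$v < 1e-18) break
  }
  best$x
}

# random proper rotation matrix from a seeded QR decomposition
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# non-degenerate random 4-point base plus a target point; distances exact
random_trilat4_instance <- function() {
  repeat {
    base <- matrix(stats::runif(12, -5, 5), 4, 3)
    if (!is_degenerate(base, 1e-4)) break
  }
  p <- stats::runif(3, -5, 5)
  list(base = base, p = p, dists = sqrt(colSums((t(base) - p)^2)))
}

random_trilat3_instance <- function() {
  repeat {
    base <- matrix(stats::runif(9, -5, 5), 3, 3)
    if (!is_degenerate(base, 1e-4)) break
    }
  repeat {
    p <- stats::runif(3, -5, 5)
    # keep the target clearly off the base plane so candidates are distinct
    v1 <- base[2, ] - base[1, ]; v2 <- base[3, ] - base[1, ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    if (abs(sum((p - base[1, ]) * nrm)) > 0.5) break
  }
  list(base = base, p = p, dists = sqrt(colSums((t(base) - p)^2)))
}

# regular unit tetrahedron in the canonical frame
unit_tetrahedron <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
        c(0.5, sqrt(3) / 6, sqrt(6) / 3))
}

expect_coords_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}
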