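test_that("net gradient vector is the exact compartment sum", {
  shape <- c(10, 10, 20)
  g <- two_node_graph(shape, gap_um = 10)
  p <- voronoi_assign(shape, c(1, 1, 1), g, "node")

  # uniform ramp: every voxel gradient (0, 5, 0); each node owns half the grid
  f <- manual_field(array(0, shape), array(5, shape), array(0, shape))
  nf <- net_gradient_vector(1, p, f)
  expect_equal(nf$vector, c(0, 5 * nf$n_voxels, 0))

  # two cancelling halves
  gx <- array(0, shape); gx[, , 1:10] <- 1; gx[, , 11:20] <- -1
  f2 <- manual_field(array(0, shape), array(0, shape), gx)
  tot <- net_gradient_vector(1, p, f2)$vector + net_gradient_vector(2, p, f2)$vector
  expect_equal(tot, c(0, 0, 0))

  # random field equals a loop-sum oracle
  set.seed(12)
  fz <- array(rnorm(prod(shape)), shape)
  fy <- array(rnorm(prod(shape)), shape)
  fx <- array(rnorm(prod(shape)), shape)
  f3 <- manual_field(fz, fy, fx)
  for (id in 1:2) {
    nf <- net_gradient_vector(id, p, f3)
    idx <- which(p$labels == id)
    oracle <- c(0, 0, 0)
    for (i in idx) oracle <- oracle + c(fz[i], fy[i], fx[i])
    expect_equal(nf$vector, oracle, tolerance = 1e-9)
    expect_equal(nf$magnitude_sum, sum(sqrt(fz[idx]^2 + fy[idx]^2 + fx[idx]^2)),
                 tolerance = 1e-9)
  }
  expect_error(net_gradient_vector(99, p, f3), "absent")
})

test_that("edge basis completion spans 3-space in every degree case", {
  # degree 1: three mutually orthogonal columns at the real edge's norm
  b1 <- complete_edge_basis(matrix(c(2, 0, 0), ncol = 1), "1-2")
  expect_equal(dim(b1$E), c(3L, 3L))
  expect_equal(b1$hypothetical, c(FALSE, TRUE, TRUE))
  G <- crossprod(b1$E)
  expect_equal(G, diag(c(4, 4, 4)), tolerance = 1e-9)

  # degree 2: hypothetical column is the (rescaled) cross product
  E2 <- cbind(c(1, 0, 0), c(0, 1, 0))
  b2 <- complete_edge_basis(E2)
  expect_equal(b2$hypothetical, c(FALSE, FALSE, TRUE))
  expect_equal(abs(b2$E[, 3]), c(0, 0, 1))
  expect_equal(abs(det(b2$E)), 1, tolerance = 1e-9)

  # degree 2 with parallel edges falls back to the degree-1 construction
  b2p <- complete_edge_basis(cbind(c(1, 0, 0), c(2, 0, 0)))
  expect_equal(sum(b2p$hypothetical), 2)
  expect_equal(qr(b2p$E)$rank, 3)

  # degree >= 3: passthrough, no hypothetical columns
  set.seed(14)
  E5 <- matrix(rnorm(15), 3, 5)
  b5 <- complete_edge_basis(E5)
  expect_equal(b5$E, E5)
  expect_false(any(b5$hypothetical))

  expect_error(complete_edge_basis(matrix(0, 3, 1)), "zero-length")
})

test_that("minimum-norm projection solves and minimizes", {
  # orthonormal basis: weights are the components
  w <- minimum_norm_projection(diag(3), c(2, 3, 4))
  expect_equal(w$weights, c(2, 3, 4))
  # zero force -> zero weights
  set.seed(15)
  E <- matrix(rnorm(15), 3, 5)
  expect_equal(minimum_norm_projection(E, c(0, 0, 0))$weights, rep(0, 5))

  # 1000 random 3x5 systems: reconstruction, pseudoinverse oracle agreement,
  # and minimality over random nullspace perturbations
  for (i in 1:1000) {
    E <- matrix(rnorm(15), 3, 5)
    F <- rnorm(3)
    w <- minimum_norm_projection(E, F)$weights
    expect_equal(as.vector(E %*% w), F, tolerance = 1e-8)
    w_oracle <- as.vector(MASS::ginv(E) %*% F) # SVD pseudoinverse route
    expect_equal(w, w_oracle, tolerance = 1e-8)
    ns <- pracma::nullspace(E) # 5x2 nullspace basis
    pert <- ns %*% rnorm(ncol(ns), 0, 2)
    expect_lte(sum(w^2), sum((w + pert)^2) + 1e-10)
  }
})

test_that("minimality holds against a quadratic-programming style oracle", {
  # minimise ||w|| s.t. E w = F via Lagrange block solve (independent route)
  set.seed(16)
  for (i in 1:50) {
    E <- matrix(rnorm(15), 3, 5)
    F <- rnorm(3)
    KKT <- rbind(cbind(diag(5), t(E)), cbind(E, matrix(0, 3, 3)))
    sol <- solve(KKT, c(rep(0, 5), F))
    w_qp <- sol[1:5]
    w <- minimum_norm_projection(E, F)$weights
    expect_equal(w, w_qp, tolerance = 1e-8)
  }
})

test_that("rank-deficient systems fall back to the pseudoinverse with warning", {
  E <- cbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(0, 1, 0))
  F <- c(1, 1, 0) # representable (no depth-axis component)
  expect_warning(w <- minimum_norm_projection(E, F), "rank-deficient|residual")
  expect_equal(as.vector(E %*% w$weights), F, tolerance = 1e-6)
})

test_that("CDL cancels opposing pulls and reports one-sided pulls", {
  shape <- c(10, 10, 20)
  g <- two_node_graph(shape, gap_um = 10) # edge along col, length 10
  p <- voronoi_assign(shape, c(1, 1, 1), g, "node")

  # mirror-symmetric field: gradients point toward the mid-plane
  gx <- array(0, shape); gx[, , 1:10] <- 2; gx[, , 11:20] <- -2
  f <- manual_field(array(0, shape), array(0, shape), gx)
  proj <- node_projections(g, p, f)
  cdl <- compute_cdl(g, proj)
  expect_equal(nrow(cdl), 1)
  expect_equal(cdl$cdl, 0, tolerance = 1e-9)

  # single-sided pull along the edge: CDL equals the projection coefficient
  gx2 <- array(0, shape); gx2[p$labels == 1L] <- 3
  f2 <- manual_field(array(0, shape), array(0, shape), gx2)
  proj2 <- node_projections(g, p, f2)
  cdl2 <- compute_cdl(g, proj2)
  w1 <- proj2[["1"]]$projection
  real <- which(!w1$hypothetical)
  expect_equal(cdl2$cdl, abs(w1$weights[real]), tolerance = 1e-9)
  # hand oracle: node 1 net force = (0,0,3*N1); edge vector from 1 is (0,0,10)
  # with orthogonal hypothetical columns, so the coefficient is |F|/|e|
  N1 <- sum(p$labels == 1L)
  expect_equal(cdl2$cdl, 3 * N1 / 10, tolerance = 1e-9)
})

test_that("CDL equals a hand-assembled vector sum on a random two-node fixture", {
  set.seed(19)
  shape <- c(8, 8, 16)
  g <- two_node_graph(shape, gap_um = 8)
  fz <- array(rnorm(prod(shape)), shape)
  fy <- array(rnorm(prod(shape)), shape)
  fx <- array(rnorm(prod(shape)), shape)
  f <- manual_field(fz, fy, fx)
  p <- voronoi_assign(shape, c(1, 1, 1), g, "node")
  proj <- node_projections(g, p, f)
  cdl <- compute_cdl(g, proj)

  # by hand: for each node solve the orthogonal 3-column system, take the
  # real-edge coefficient times the outgoing unit edge vector, sum, norm
  total <- c(0, 0, 0)
  for (id in 1:2) {
    Fv <- net_gradient_vector(id, p, f)$vector
    ev <- edge_vector(g, 1, 2, origin_node = id)
    coef <- sum(Fv * ev) / sum(ev^2) # orthogonal basis -> least-squares component
    total <- total + coef * ev / sqrt(sum(ev^2))
  }
  expect_equal(cdl$cdl, sqrt(sum(total^2)), tolerance = 1e-9)
})

test_that("GDL arithmetic, normalization law, and degenerate cases", {
  cdl <- tibble::tibble(u = c(1, 2), v = c(2, 3), cdl = c(1, 3))
  expect_equal(compute_gdl(cdl, 1000), 0.004)
  expect_equal(compute_gdl(tibble::tibble(u = 1, v = 2, cdl = 0), 500), 0)
  expect_equal(compute_gdl(cdl, 2000), compute_gdl(cdl, 1000) / 2)
  expect_warning(g0 <- compute_gdl(tibble::tibble(u = integer(), v = integer(),
                                                  cdl = numeric()), 100),
                 "empty")
  expect_equal(g0, 0)
  # physical normalization divides by volume
  expect_equal(compute_gdl(cdl, 1000, spacing_um = c(2, 1, 1), physical = TRUE),
               0.002)
})

test_that("a zero-gradient field yields GDL 0 and filtering mirrors highlighting", {
  shape <- c(8, 8, 16)
  g <- two_node_graph(shape, gap_um = 8)
  p <- voronoi_assign(shape, c(1, 1, 1), g, "node")
  f0 <- manual_field(array(0, shape), array(0, shape), array(0, shape))
  cdl <- compute_cdl(g, node_projections(g, p, f0))
  expect_equal(compute_gdl(cdl, prod(shape)), 0)

  sub <- filter_cdl_edges(g, tibble::tibble(u = 1, v = 2, cdl = 0.4), 0.3)
  expect_equal(nrow(sub$edges), 1)
  sub2 <- filter_cdl_edges(g, tibble::tibble(u = 1, v = 2, cdl = 0.2), 0.3)
  expect_equal(nrow(sub2$edges), 0)
})

test_that("progressively cancelling forces give monotonically decreasing GDL", {
  shape <- c(10, 10, 20)
  g <- two_node_graph(shape, gap_um = 10)
  p <- voronoi_assign(shape, c(1, 1, 1), g, "node")
  prev <- Inf
  for (cancel in c(0, 0.25, 0.5, 0.75, 1)) {
    # node 1 pulls +x with strength 2; node 2 opposes with fraction `cancel`
    gx <- array(0, shape)
    gx[p$labels == 1L] <- 2
    gx[p$labels == 2L] <- -2 * cancel
    f <- manual_field(array(0, shape), array(0, shape), gx)
    gdl <- compute_gdl(compute_cdl(g, node_projections(g, p, f)), prod(shape))
    expect_lt(gdl, prev)
    prev <- gdl
  }
  expect_equal(prev, 0, tolerance = 1e-9)
})
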