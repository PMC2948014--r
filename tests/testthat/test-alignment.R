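test_that("gradient of a linear ramp is the slope along that axis", {
  for (axis in 1:3) {
    s <- ramp_stack(c(6, 6, 6), axis, slope = 5)
    f <- gradient_field(s)
    comp <- list(f$gz, f$gy, f$gx)
    expect_equal(comp[[axis]], array(5, c(6, 6, 6)))
    for (other in setdiff(1:3, axis)) {
      expect_equal(comp[[other]], array(0, c(6, 6, 6)))
    }
    expect_equal(f$magnitude, array(5, c(6, 6, 6)))
  }
  # constant image -> zero field
  f0 <- gradient_field(image_stack(array(42, c(4, 4, 4))))
  expect_equal(f0$magnitude, array(0, c(4, 4, 4)))
})

test_that("gradient matches a naive finite-difference loop oracle", {
  set.seed(4)
  a <- array(runif(729, 0, 100), c(9, 9, 9))
  sp <- c(2, 1, 0.5)
  f <- gradient_field(image_stack(a, sp))
  d <- function(i, n) c(max(i - 1, 1), min(i + 1, n)) # one-sided at borders
  for (trial in 1:200) {
    ix <- sapply(c(9, 9, 9), function(n) sample(n, 1))
    i <- ix[1]; j <- ix[2]; k <- ix[3]
    zz <- d(i, 9); gz <- (a[zz[2], j, k] - a[zz[1], j, k]) / ((zz[2] - zz[1]) * sp[1])
    yy <- d(j, 9); gy <- (a[i, yy[2], k] - a[i, yy[1], k]) / ((yy[2] - yy[1]) * sp[2])
    xx <- d(k, 9); gx <- (a[i, j, xx[2]] - a[i, j, xx[1]]) / ((xx[2] - xx[1]) * sp[3])
    expect_equal(f$gz[i, j, k], gz, tolerance = 1e-12)
    expect_equal(f$gy[i, j, k], gy, tolerance = 1e-12)
    expect_equal(f$gx[i, j, k], gx, tolerance = 1e-12)
    expect_equal(f$magnitude[i, j, k], sqrt(gz^2 + gy^2 + gx^2), tolerance = 1e-12)
  }
})

test_that("angle_between covers the canonical cases and rejects zero vectors", {
  expect_equal(angle_between(c(0, 1, 0), c(1, 0, 0)), 90)
  expect_lt(angle_between(c(1, 1, 0), c(2, 2, 0)), 1e-5) # acos precision floor
  expect_equal(angle_between(c(1, 0, 0), c(-3, 0, 0)), 180)
  expect_equal(angle_between(c(1, 0, 0), c(1, 1, 0)), 45, tolerance = 1e-12)
  expect_equal(angle_between(c(1, 2, 3), c(3, -1, 2)),
               angle_between(c(3, -1, 2), c(1, 2, 3)))
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("angle_distribution normalizes to a pdf and respects bins", {
  d <- angle_distribution(c(90, 90, 10), weights = c(2, 4, 5), bins = 180)
  expect_equal(sum(d$pdf), 1, tolerance = 1e-9)
  expect_true(all(d$pdf >= 0))
  expect_equal(d$total_weight, 11)
  # 90 lies on a bin edge -> accumulated into the [90, 91) bin, centre 90.5
  expect_equal(d$bin_center[which.max(d$weight)], 90.5)
  expect_equal(sum(d$weight > 0), 2)
  # 180 is included via the closed last bin
  d2 <- angle_distribution(c(0, 180), bins = 180)
  expect_equal(sum(d2$weight), 2)
})

test_that("a ramp perpendicular to the edge puts all mass at 90 degrees", {
  g <- two_node_graph(c(24, 24, 24), gap_um = 12)
  s <- ramp_stack(c(24, 24, 24), axis = 2, slope = 5) # gradient along row, edge along col
  p <- voronoi_assign(c(24, 24, 24), c(1, 1, 1), g, "edge_midpoint")
  f <- gradient_field(s)
  d <- edge_angle_distribution(g, 1, 2, p, f)
  expect_true(d$usable)
  expect_equal(sum(d$pdf[d$bin_center > 89 & d$bin_center < 92]), 1, tolerance = 1e-12)
  cai <- collagen_alignment_index(d)
  expect_equal(cai$cai, 1)
})

test_that("two equal-weight gradient populations split the pdf 50/50", {
  shape <- c(10, 10, 20)
  g <- two_node_graph(shape, gap_um = 10)
  gz <- array(0, shape); gy <- array(0, shape); gx <- array(0, shape)
  gy[, , 1:10] <- 3   # perpendicular to the col-axis edge: 90 degrees
  gx[, , 11:20] <- 3  # parallel: 0 degrees
  f <- manual_field(gz, gy, gx)
  p <- voronoi_assign(shape, c(1, 1, 1), g, "edge_midpoint")
  d <- edge_angle_distribution(g, 1, 2, p, f)
  expect_equal(d$pdf[d$bin_center == 0.5], 0.5, tolerance = 1e-12)
  expect_equal(d$pdf[d$bin_center == 90.5], 0.5, tolerance = 1e-12)
  # doubling intensities leaves the pdf unchanged
  f2 <- manual_field(2 * gz, 2 * gy, 2 * gx)
  d2 <- edge_angle_distribution(g, 1, 2, p, f2)
  expect_equal(d2$pdf, d$pdf, tolerance = 1e-12)
  expect_equal(d2$total_weight, 2 * d$total_weight)
})

test_that("CAI window arithmetic: delta distributions and closed forms", {
  all90 <- angle_distribution(rep(90, 100), runif(100, 0.5, 2))
  expect_equal(collagen_alignment_index(all90)$cai, 1)
  all0 <- angle_distribution(rep(0, 100))
  expect_equal(collagen_alignment_index(all0)$cai, 0)
  expect_error(collagen_alignment_index(angle_distribution(numeric())), "zero")

  # uniform directions on the 3D sphere: P(60 <= theta <= 120) = 1/2
  set.seed(6)
  dirs <- random_directions(1e6)
  theta <- acos(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi # angle to col axis
  cai3d <- collagen_alignment_index(angle_distribution(theta))$cai
  expect_equal(cai3d, 0.5, tolerance = 0.01)

  # directions uniform in a plane containing the edge: theta ~ U[0,180] -> 1/3
  phi <- runif(1e6, 0, 180)
  cai2d <- collagen_alignment_index(angle_distribution(phi))$cai
  expect_equal(cai2d, 1 / 3, tolerance = 0.01)
})

test_that("CAI increases strictly with the perpendicular fraction", {
  set.seed(31)
  n <- 2e4
  dirs <- random_directions(n)
  theta_rand <- acos(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi
  prev <- -1
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    k <- round(f * n)
    theta <- c(rep(90, k), theta_rand[seq_len(n - k)])
    cai <- collagen_alignment_index(angle_distribution(theta))$cai
    expect_gt(cai, prev)
    prev <- cai
  }
  expect_equal(prev, 1)
})

test_that("pooling matches single-edge results and is order invariant", {
  shape <- c(16, 16, 32)
  g <- two_node_graph(shape, gap_um = 16)
  s <- ramp_stack(shape, axis = 2)
  p <- voronoi_assign(shape, c(1, 1, 1), g, "edge_midpoint")
  f <- gradient_field(s)
  single <- edge_angle_distribution(g, 1, 2, p, f)
  pooled <- sample_angle_distribution(g, p, f)
  expect_equal(pooled$pdf, single$pdf)
  expect_equal(pooled$total_weight, single$total_weight)

  # two edges, equal total magnitude, one all-90 one all-0 -> pooled CAI 0.5
  # (node 3 offset by a half voxel so no voxel is equidistant to the two
  # edge midpoints and the partition is tie-free)
  pts <- rbind(c(2, 2, 2), c(2, 2, 12), c(2, 12.5, 2))
  g3 <- build_cell_graph(pts, 11)
  expect_equal(nrow(g3$edges), 2)
  shape3 <- c(5, 15, 15)
  p3 <- voronoi_assign(shape3, c(1, 1, 1), g3, "edge_midpoint")
  cs <- compartment_sizes(p3)
  gz <- array(0, shape3); gy <- array(0, shape3); gx <- array(0, shape3)
  # edge 1 runs along col; edge 2 along row. Give every voxel of compartment 1
  # a gradient along row (90 deg to edge 1) and compartment 2 along itself
  m1 <- p3$labels == 1L; m2 <- p3$labels == 2L
  gy[m1] <- 1 / sum(m1) # equalize total magnitude between compartments
  gy[m2] <- 1 / sum(m2) # parallel to edge 2 -> 0 degrees
  f3 <- manual_field(gz, gy, gx)
  pooled3 <- sample_angle_distribution(g3, p3, f3)
  expect_equal(collagen_alignment_index(pooled3)$cai, 0.5, tolerance = 1e-12)

  # permuting edge order leaves the pooled pdf unchanged
  g3r <- g3
  g3r$edges <- g3r$edges[2:1, ]
  p3r <- voronoi_assign(shape3, c(1, 1, 1), g3r, "edge_midpoint")
  pooled3r <- sample_angle_distribution(g3r, p3r, f3)
  expect_equal(pooled3r$pdf, pooled3$pdf, tolerance = 1e-12)
})

test_that("angle distributions are preserved under an exact 90-degree rotation", {
  shape <- c(8, 20, 20)
  # original: edge along col, ramp along row
  g1 <- build_cell_graph(rbind(c(4, 10, 4), c(4, 10, 16)), 20)
  s1 <- ramp_stack(shape, axis = 2, slope = 3)
  p1 <- voronoi_assign(shape, c(1, 1, 1), g1, "edge_midpoint")
  d1 <- sample_angle_distribution(g1, p1, gradient_field(s1))
  # rotated about the depth axis: swap row/col axes (rotation-exact fixture)
  g2 <- build_cell_graph(rbind(c(4, 4, 10), c(4, 16, 10)), 20)
  s2 <- image_stack(aperm(s1$voxels, c(1, 3, 2)))
  p2 <- voronoi_assign(shape, c(1, 1, 1), g2, "edge_midpoint")
  d2 <- sample_angle_distribution(g2, p2, gradient_field(s2))
  expect_equal(d2$pdf, d1$pdf, tolerance = 1e-12)
})

test_that("an all-zero-gradient compartment is flagged unusable", {
  shape <- c(8, 8, 16)
  g <- two_node_graph(shape, gap_um = 8)
  f0 <- gradient_field(image_stack(array(5, shape)))
  p <- voronoi_assign(shape, c(1, 1, 1), g, "edge_midpoint")
  expect_warning(d <- edge_angle_distribution(g, 1, 2, p, f0), "all-zero")
  expect_false(d$usable)
  expect_error(suppressWarnings(sample_angle_distribution(g, p, f0)), "usable")
})
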