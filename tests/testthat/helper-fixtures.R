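# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures on disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack whose intensity is a linear ramp along one axis (1 = depth, 2 = row,
# 3 = col): I = slope * coordinate_um + offset
ramp_stack <- function(shape, axis, slope = 5, offset = 100,
                       spacing_um = c(1, 1, 1)) {
  co <- seq_len(shape[axis]) - 1
  a <- array(0, shape)
  per <- c(1, 2, 3)
  vals <- slope * co * spacing_um[axis] + offset
  a <- aperm(array(rep(vals, prod(shape[-axis])),
                   c(shape[axis], shape[-axis])),
             order(c(axis, per[-axis])))
  image_stack(a, spacing_um)
}

# two-node graph along the col (x) axis, centred in a cubic grid
two_node_graph <- function(shape = c(32, 32, 32), gap_um = 20,
                           spacing_um = c(1, 1, 1)) {
  mid <- (shape - 1) * spacing_um / 2
  x0 <- mid[3] - gap_um / 2
  pts <- rbind(c(mid[1], mid[2], x0), c(mid[1], mid[2], x0 + gap_um))
  build_cell_graph(pts, link_threshold_um = gap_um + 1)
}

# hand-constructed gradient field (bypasses finite differences) for tests
# that need exact per-voxel gradients
manual_field <- function(gz, gy, gx, spacing_um = c(1, 1, 1)) {
  structure(
    list(gz = gz, gy = gy, gx = gx,
         magnitude = sqrt(gz^2 + gy^2 + gx^2),
         spacing_um = spacing_um),
    class = "gradient_field"
  )
}

# brute-force nearest-seed labels over voxel centres (the Voronoi oracle)
brute_voronoi <- function(shape, spacing_um, seeds, shift = c(0, 0, 0)) {
  co <- expand.grid(
    d1 = (seq_len(shape[1]) - 1) * spacing_um[1] + shift[1],
    d2 = (seq_len(shape[2]) - 1) * spacing_um[2] + shift[2],
    d3 = (seq_len(shape[3]) - 1) * spacing_um[3] + shift[3]
  )
  co <- as.matrix(co)
  lab <- integer(nrow(co))
  for (i in seq_len(nrow(co))) {
    d2 <- rowSums(sweep(seeds, 2, co[i, ])^2)
    lab[i] <- which.min(d2) # first minimum = lowest label
  }
  array(lab, shape)
}

# brute-force exhaustive Otsu on a discrete histogram (values + counts):
# returns the threshold minimising the intra-class variance, lowest-threshold
# tie break. Independent loop implementation.
brute_otsu <- function(values, counts) {
  n <- sum(counts)
  best_t <- NA_real_; best_v <- Inf
  for (ci in seq_len(length(values) - 1)) {
    m1 <- rep(values[1:ci], counts[1:ci])
    m2 <- rep(values[(ci + 1):length(values)], counts[(ci + 1):length(values)])
    p1 <- length(m1) / n; p2 <- length(m2) / n
    v1 <- if (length(m1) > 1) mean((m1 - mean(m1))^2) else 0
    v2 <- if (length(m2) > 1) mean((m2 - mean(m2))^2) else 0
    wcv <- p1 * v1 + p2 * v2
    if (wcv < best_v - 1e-12) {
      best_v <- wcv; best_t <- values[ci]
    }
  }
  list(threshold = best_t, wcv = best_v)
}

# random unit vectors (independent of the package's internal sampler)
random_directions <- function(n) {
  m <- cbind(rnorm(n), rnorm(n), rnorm(n))
  m / sqrt(rowSums(m^2))
}

# planted pdf matrix: 3 groups x `per_group` rows over `bins` bins
planted_pdf_matrix <- function(per_group = 3, bins = 60, noise = 0.02) {
  grid <- seq(0, 180, length.out = bins)
  flat <- rep(1, bins)
  peaked <- exp(-0.5 * ((grid - 90) / 8)^2)
  bimodal <- exp(-0.5 * ((grid - 30) / 8)^2) + exp(-0.5 * ((grid - 150) / 8)^2)
  base <- list(flat, peaked, bimodal)
  rows <- list(); labels <- integer()
  for (g in 1:3) {
    for (r in seq_len(per_group)) {
      v <- base[[g]] + abs(rnorm(bins, 0, noise))
      rows[[length(rows) + 1]] <- v / sum(v)
      labels <- c(labels, g)
    }
  }
  list(X = do.call(rbind, rows), labels = labels)
}

# do two partitions agree exactly (up to label permutation)?
partitions_agree <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
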