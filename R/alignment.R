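#' Per-voxel intensity gradient field of a stack
#'
#' Finite-difference gradient of the collagen (SHG) channel: central
#' differences in the interior, one-sided differences at the boundary
#' planes, each axis divided by its physical spacing so components are in
#' intensity per um. The gradient vector points in the direction of
#' maximal intensity increase; its magnitude is the local rate of change
#' and is used downstream as the weight of that voxel's orientation.
#'
#' @param stack an [image_stack()] with every dimension >= 2.
#' @param drop_boundary if `TRUE`, the magnitudes of the outermost voxel
#'   shell are set to 0 so one-sided estimates never contribute weight.
#' @return A `gradient_field`: list of arrays `gz`, `gy`, `gx` (components
#'   along depth, row, col), `magnitude`, and `spacing_um`.
#' @export
gradient_field <- function(stack, drop_boundary = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$voxels
  dm <- dim(a)
  if (any(dm < 2L)) stop("gradient needs >= 2 voxels along every axis", call. = FALSE)
  sp <- stack$spacing_um
  gz <- diff_axis(a, 1L, sp[1])
  gy <- diff_axis(a, 2L, sp[2])
  gx <- diff_axis(a, 3L, sp[3])
  mag <- sqrt(gz^2 + gy^2 + gx^2)
  if (drop_boundary) {
    if (any(dm < 3L)) stop("drop_boundary needs >= 3 voxels along every axis", call. = FALSE)
    shell <- array(TRUE, dm)
    shell[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)] <- FALSE
    gz[shell] <- 0; gy[shell] <- 0; gx[shell] <- 0; mag[shell] <- 0
  }
  structure(
    list(gz = gz, gy = gy, gx = gx, magnitude = mag, spacing_um = sp),
    class = "gradient_field"
  )
}

# central differences along `axis`, one-sided at the two boundary planes
diff_axis <- function(a, axis, spacing) {
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  dmp <- dim(b)
  n <- dmp[1]
  m <- matrix(b, nrow = n)
  g <- matrix(0, nrow = n, ncol = ncol(m))
  if (n == 2L) {
    d <- (m[2, ] - m[1, ]) / spacing
    g[1, ] <- d; g[2, ] <- d
  } else {
    g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * spacing)
    g[1, ] <- (m[2, ] - m[1, ]) / spacing
    g[n, ] <- (m[n, ] - m[n - 1, ]) / spacing
  }
  aperm(array(g, dmp), order(perm))
}

#' @export
print.gradient_field <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<gradient_field> %d x %d x %d voxels, max |g| = %.4g /um\n",
              d[1], d[2], d[3], max(x$magnitude)))
  invisible(x)
}

#' Unsigned angle between two 3-vectors, in degrees
#'
#' `acos` of the cosine similarity, clamped to `[-1, 1]` for numerical
#' safety; the result lies in `[0, 180]` and is symmetric in its
#' arguments. An angle of 90 degrees between a voxel gradient and a
#' cell-graph edge marks perfect collagen alignment.
#'
#' @param g,e non-zero numeric 3-vectors.
#' @return Angle in degrees.
#' @examples
#' angle_between(c(0, 1, 0), c(1, 0, 0)) # 90
#' @export
angle_between <- function(g, e) {
  ng <- sqrt(sum(g^2)); ne <- sqrt(sum(e^2))
  if (ng == 0 || ne == 0) stop("angle with a zero vector is undefined", call. = FALSE)
  acos(max(-1, min(1, sum(g * e) / (ng * ne)))) * 180 / pi
}

# vectorised: angles (deg) between rows of matrix G and a single vector e;
# rows with zero norm give NA
angles_to_vector <- function(G, e) {
  ne <- sqrt(sum(e^2))
  ng <- sqrt(rowSums(G^2))
  cosv <- as.vector(G %*% e) / (ng * ne)
  out <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  out[ng == 0] <- NA_real_
  out
}

#' Magnitude-weighted angle histogram over [0, 180] degrees
#'
#' Accumulates angle/weight pairs into `bins` uniform bins spanning
#' `[0, 180]` degrees (half-open on the left except the last bin, which
#' is closed so 180 is included) and normalizes the weights by the total
#' accumulated weight to form a probability density over bins.
#'
#' @param theta_deg numeric vector of angles in `[0, 180]`.
#' @param weights non-negative weights (gradient magnitudes); default 1.
#' @param bins number of bins (default 180, i.e. 1-degree bins, fine
#'   enough that the `[60, 120]` CAI window is bin-aligned).
#' @return An `angle_distribution`: list with `bin_edges`, `bin_center`,
#'   `weight` (summed weights per bin), `pdf` (weights / total), `total
#'   _weight`, `n_values`, and `usable` (`FALSE` when total weight is 0).
#' @export
angle_distribution <- function(theta_deg, weights = NULL, bins = 180L) {
  bins <- as.integer(bins)
  stopifnot(bins >= 2L)
  if (is.null(weights)) weights <- rep(1, length(theta_deg))
  stopifnot(length(weights) == length(theta_deg))
  ok <- is.finite(theta_deg) & is.finite(weights)
  theta_deg <- theta_deg[ok]; weights <- weights[ok]
  if (any(theta_deg < 0 | theta_deg > 180)) {
    stop("angles must lie in [0, 180] degrees", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  edges <- seq(0, 180, length.out = bins + 1L)
  bin <- findInterval(theta_deg, edges, rightmost.closed = TRUE)
  w <- numeric(bins)
  if (length(bin)) {
    acc <- rowsum(weights, group = bin)
    w[as.integer(rownames(acc))] <- acc[, 1]
  }
  tot <- sum(w)
  structure(
    list(
      bin_edges = edges,
      bin_center = (edges[-1] + edges[-(bins + 1L)]) / 2,
      weight = w,
      pdf = if (tot > 0) w / tot else rep(0, bins),
      total_weight = tot,
      n_values = length(theta_deg),
      usable = tot > 0
    ),
    class = "angle_distribution"
  )
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf(
    "<angle_distribution> %d bins over [0,180] deg, %d values, total weight %.4g%s\n",
    length(x$weight), x$n_values, x$total_weight,
    if (!x$usable) " (unusable: zero weight)" else ""))
  invisible(x)
}

# pool several angle distributions on identical bins (weights add; pdf
# renormalised)
pool_distributions <- function(dists) {
  dists <- dists[!vapply(dists, is.null, logical(1))]
  stopifnot(length(dists) >= 1L)
  w <- Reduce(`+`, lapply(dists, `[[`, "weight"))
  d <- dists[[1]]
  d$weight <- w
  d$total_weight <- sum(w)
  d$pdf <- if (d$total_weight > 0) w / d$total_weight else rep(0, length(w))
  d$n_values <- sum(vapply(dists, `[[`, numeric(1), "n_values"))
  d$usable <- d$total_weight > 0
  d
}

#' Angle distribution of one edge's Voronoi compartment
#'
#' For every voxel of the edge-midpoint Voronoi compartment belonging to
#' edge `(u, v)` whose gradient magnitude is positive, the angle between
#' the voxel gradient and the edge vector is accumulated with the gradient
#' magnitude as weight.
#'
#' @param graph a `cell_graph`.
#' @param u,v endpoints of an edge of `graph`.
#' @param partition edge-midpoint-mode `partition_volume` over the same
#'   grid as `field`.
#' @param field a `gradient_field` of the collagen channel.
#' @param bins histogram bins (default 180).
#' @return An `angle_distribution`; `usable = FALSE` (with a warning) when
#'   the compartment is empty or all its gradients vanish.
#' @export
edge_angle_distribution <- function(graph, u, v, partition, field, bins = 180L) {
  stopifnot(inherits(partition, "partition_volume"),
            partition$mode == "edge_midpoint",
            inherits(field, "gradient_field"))
  lab <- edge_label(partition, u, v)
  if (is.na(lab)) stop(sprintf("edge (%s, %s) owns no compartment", u, v), call. = FALSE)
  ev <- edge_vector(graph, u, v)
  idx <- compartment_indices(partition, lab)
  mag <- field$magnitude[idx]
  keep <- mag > 0
  if (!length(idx) || !any(keep)) {
    warning(sprintf("edge (%s, %s): empty compartment or all-zero gradients", u, v))
    return(angle_distribution(numeric(), numeric(), bins = bins))
  }
  G <- cbind(field$gz[idx][keep], field$gy[idx][keep], field$gx[idx][keep])
  theta <- angles_to_vector(G, ev)
  angle_distribution(theta, mag[keep], bins = bins)
}

#' Pooled angle distribution of a whole sample
#'
#' Accumulates angle/weight pairs across the compartments of every edge
#' before normalizing, so the pooled pdf weights each voxel by its
#' gradient magnitude regardless of which edge owns it. The sample CAI is
#' computed from this pooled pdf.
#'
#' @inheritParams edge_angle_distribution
#' @return A pooled `angle_distribution`.
#' @export
sample_angle_distribution <- function(graph, partition, field, bins = 180L) {
  stopifnot(nrow(graph$edges) >= 1L)
  dists <- purrr::map2(graph$edges$u, graph$edges$v, function(u, v) {
    suppressWarnings(edge_angle_distribution(graph, u, v, partition, field, bins))
  })
  pooled <- pool_distributions(dists)
  if (!pooled$usable) stop("no usable edge compartment in sample", call. = FALSE)
  pooled
}

#' Collagen Alignment Index
#'
#' The CAI of an angle distribution is the probability mass falling in
#' bins whose centres lie inside `[lo_deg, hi_deg]` (default
#' `[60, 120]`). It equals 1 when all gradient mass is perpendicular to
#' the cell-graph edges (perfect alignment) and about 0.5 for gradient
#' directions uniform on the 3D sphere.
#'
#' @param dist an `angle_distribution` with positive total weight.
#' @param lo_deg,hi_deg window bounds in degrees (inclusive, by bin
#'   centre).
#' @return A `cai_result`: list with `cai`, `lo_deg`, `hi_deg`,
#'   `n_voxels_used`.
#' @export
collagen_alignment_index <- function(dist, lo_deg = 60, hi_deg = 120) {
  stopifnot(inherits(dist, "angle_distribution"))
  if (!dist$usable) stop("angle distribution has zero total weight", call. = FALSE)
  stopifnot(lo_deg < hi_deg)
  inside <- dist$bin_center >= lo_deg & dist$bin_center <= hi_deg
  structure(
    list(cai = sum(dist$pdf[inside]), lo_deg = lo_deg, hi_deg = hi_deg,
         n_voxels_used = dist$n_values),
    class = "cai_result"
  )
}

#' @export
print.cai_result <- function(x, ...) {
  cat(sprintf("<cai_result> CAI = %.4f over [%g, %g] deg (%d voxels)\n",
              x$cai, x$lo_deg, x$hi_deg, x$n_voxels_used))
  invisible(x)
}

#' Per-edge CAI table
#'
#' @inheritParams edge_angle_distribution
#' @param lo_deg,hi_deg CAI window (degrees).
#' @return Tibble `u`, `v`, `cai`, `n_voxels`; edges with unusable
#'   compartments get `NA`.
#' @export
edge_cai_table <- function(graph, partition, field, bins = 180L,
                           lo_deg = 60, hi_deg = 120) {
  purrr::map2_dfr(graph$edges$u, graph$edges$v, function(u, v) {
    d <- suppressWarnings(edge_angle_distribution(graph, u, v, partition, field, bins))
    if (d$usable) {
      r <- collagen_alignment_index(d, lo_deg, hi_deg)
      tibble::tibble(u = u, v = v, cai = r$cai, n_voxels = d$n_values)
    } else {
      tibble::tibble(u = u, v = v, cai = NA_real_, n_voxels = 0L)
    }
  })
}
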