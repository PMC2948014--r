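#' Specification for synthetic two-channel fixtures
#'
#' Describes a synthetic acquisition emulating a two-channel 3D stack:
#' a nuclei channel with Gaussian-profile ellipsoidal blobs at known
#' centroids, and a collagen (SHG-like) channel made of sinusoidal stripe
#' fields whose per-voxel gradient direction is controlled relative to
#' the local cell-graph edge. All randomness is fixed by `seed`.
#'
#' @param shape grid dimensions (depth, row, col). Default `c(48,48,48)`.
#' @param spacing_um voxel spacing in um.
#' @param centroids planted nucleus centres: n x 3 matrix in um, axis
#'   order (depth, row, col); `NULL` draws `n_nuclei` centres uniformly
#'   with a minimum pairwise separation.
#' @param n_nuclei number of nuclei drawn when `centroids` is `NULL`.
#' @param min_separation_um minimum centre separation for drawn centroids.
#' @param nucleus_radius_um Gaussian sd of the blob profile per axis (um).
#' @param peak blob peak intensity above background.
#' @param background constant background intensity.
#' @param noise_sd sd of additive Gaussian noise (0 = noise-free).
#' @param fiber_mode `"perpendicular"`, `"parallel"`, `"uniform3d"` or
#'   `"mixture"`: orientation of stripe gradients relative to the local
#'   edge axis. `"mixture"` mixes perpendicular and uniform-random blocks
#'   at fraction `mixture_fraction`.
#' @param mixture_fraction fraction `f` of perpendicular-gradient blocks
#'   in mixture mode, in `[0, 1]`.
#' @param stripe_wavelength_um stripe period (um). Default 12, large
#'   enough that finite-difference gradient directions track the analytic
#'   stripe normal closely.
#' @param stripe_amplitude stripe intensity amplitude.
#' @param ramp_gradient slope (intensity per um) of a linear ramp along
#'   the row axis added to the collagen channel; a non-zero value plants
#'   a non-cancelling net pull on every cell (used to control GDL).
#' @param seed integer; fixes every random draw.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(48, 48, 48),
                           spacing_um = c(1, 1, 1),
                           centroids = NULL,
                           n_nuclei = 8L,
                           min_separation_um = 12,
                           nucleus_radius_um = c(3, 3, 3),
                           peak = 3000,
                           background = 100,
                           noise_sd = 0,
                           fiber_mode = c("perpendicular", "parallel",
                                          "uniform3d", "mixture"),
                           mixture_fraction = 0.5,
                           stripe_wavelength_um = 12,
                           stripe_amplitude = 1000,
                           ramp_gradient = 0,
                           seed = 1L) {
  fiber_mode <- match.arg(fiber_mode)
  shape <- as.integer(shape)
  spacing_um <- as.numeric(spacing_um)
  stopifnot(length(shape) == 3L, all(shape >= 2L),
            all(spacing_um > 0),
            mixture_fraction >= 0, mixture_fraction <= 1,
            stripe_wavelength_um > 0, stripe_amplitude >= 0,
            peak > 0, background >= 0, noise_sd >= 0)
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    stopifnot(ncol(centroids) == 3L)
    lim <- (shape - 1) * spacing_um
    if (any(centroids < 0) || any(sweep(centroids, 2, lim) > 0)) {
      stop("planted centroids fall outside the image bounds", call. = FALSE)
    }
  }
  structure(
    list(shape = shape, spacing_um = spacing_um, centroids = centroids,
         n_nuclei = as.integer(n_nuclei),
         min_separation_um = min_separation_um,
         nucleus_radius_um = rep_len(as.numeric(nucleus_radius_um), 3L),
         peak = peak, background = background, noise_sd = noise_sd,
         fiber_mode = fiber_mode, mixture_fraction = mixture_fraction,
         stripe_wavelength_um = stripe_wavelength_um,
         stripe_amplitude = stripe_amplitude,
         ramp_gradient = ramp_gradient, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# draw n centres uniformly in the physical box with minimum separation
draw_centroids <- function(spec) {
  lim <- (spec$shape - 1) * spec$spacing_um
  margin <- pmin(3 * spec$nucleus_radius_um, 0.15 * lim)
  lo <- margin
  hi <- lim - margin
  pts <- matrix(numeric(), ncol = 3)
  tries <- 0L
  while (nrow(pts) < spec$n_nuclei && tries < 20000L) {
    cand <- stats::runif(3, lo, hi)
    if (!nrow(pts) ||
        min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= spec$min_separation_um) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1L
  }
  if (nrow(pts) < spec$n_nuclei) {
    stop("could not place all nuclei with the requested separation", call. = FALSE)
  }
  unname(pts)
}

#' Generate the nuclei channel with planted ground truth
#'
#' Gaussian-profile ellipsoidal blobs over a constant background, plus
#' optional additive Gaussian noise (clamped at 0). The planted centroid
#' table is returned alongside the stack.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `stack` (an [image_stack()]) and `truth` (tibble
#'   `id`, `x_um`, `y_um`, `z_um`). Overlapping blobs (centres closer
#'   than 4 radii) trigger a warning.
#' @export
generate_nuclei_channel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    cen <- spec$centroids %||% draw_centroids(spec)
    if (nrow(cen) >= 2L) {
      dmin <- min(stats::dist(cen))
      if (dmin < 4 * max(spec$nucleus_radius_um)) {
        warning("planted blobs overlap (min separation ", signif(dmin, 3), " um)")
      }
    }
    co <- voxel_centers_um(spec$shape, spec$spacing_um)
    a <- array(spec$background, spec$shape)
    for (i in seq_len(nrow(cen))) {
      q <- sweep(co, 2, cen[i, ])
      q <- sweep(q, 2, spec$nucleus_radius_um, "/")
      a <- a + spec$peak * array(exp(-0.5 * rowSums(q^2)), spec$shape)
    }
    if (spec$noise_sd > 0) {
      a <- a + array(stats::rnorm(length(a), 0, spec$noise_sd), spec$shape)
      a[a < 0] <- 0
    }
    list(
      stack = image_stack(a, spec$spacing_um, "nuclei"),
      truth = tibble::tibble(
        id = seq_len(nrow(cen)),
        x_um = cen[, 3], y_um = cen[, 2], z_um = cen[, 1]
      )
    )
  })
}

# unit vector
unitize <- function(v) v / sqrt(sum(v^2))

# random unit vectors on the 3D sphere, n x 3
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Generate the collagen channel as oriented stripe fields
#'
#' The voxel grid is split into the edge-midpoint Voronoi compartments of
#' `graph`, and each compartment is tiled with cubic blocks (side = one
#' stripe wavelength). Every block receives a sinusoidal stripe field
#' `background + A * sin(2*pi * (r . k) / lambda + phase)` whose normal
#' `k` is chosen per `fiber_mode`: perpendicular or parallel to the
#' compartment's edge axis, uniform random on the sphere, or a mixture
#' (perpendicular with probability `mixture_fraction`). A linear ramp of
#' slope `ramp_gradient` along the row axis can be superimposed to plant
#' a net, non-cancelling pull on every cell. The analytic gradient
#' direction of the noise-free pattern inside a block is `+/- k` (plus
#' the constant ramp contribution).
#'
#' Block membership in mixture mode is decided by thresholding one fixed
#' uniform draw per block against `mixture_fraction`, so specs differing
#' only in `f` have nested perpendicular block sets.
#'
#' @param spec a [synthetic_spec()].
#' @param graph a `cell_graph` with at least one edge for the
#'   edge-aligned modes.
#' @return An [image_stack()]; attribute `truth` records the per-block
#'   stripe normals (`block_table`) and the block index array.
#' @export
generate_collagen_channel <- function(spec, graph) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(graph, "cell_graph"))
  if (nrow(graph$edges) == 0L &&
      spec$fiber_mode %in% c("perpendicular", "parallel", "mixture")) {
    stop("edge-aligned fiber modes need a graph with edges", call. = FALSE)
  }
  withr::with_seed(spec$seed + 1L, {
    shape <- spec$shape
    sp <- spec$spacing_um
    co <- voxel_centers_um(shape, sp)
    a <- array(spec$background, shape)

    # block index per voxel: cubic tiles of side one wavelength
    side <- pmax(1L, round(spec$stripe_wavelength_um / sp))
    ai <- arrayInd(seq_len(prod(shape)), shape)
    b1 <- (ai[, 1] - 1L) %/% side[1]
    b2 <- (ai[, 2] - 1L) %/% side[2]
    b3 <- (ai[, 3] - 1L) %/% side[3]
    nb <- c(max(b1), max(b2), max(b3)) + 1L
    block <- b1 + nb[1] * (b2 + nb[2] * b3) + 1L

    part <- if (nrow(graph$edges)) {
      suppressWarnings(voronoi_assign(shape, sp, graph, "edge_midpoint"))
    } else NULL
    comp <- if (is.null(part)) rep(1L, prod(shape)) else as.vector(part$labels)

    # coherent (edge-aligned) modes use one stripe field per compartment;
    # randomized modes draw an orientation per (compartment, block) tile
    use_blocks <- spec$fiber_mode %in% c("uniform3d", "mixture")
    cell <- if (use_blocks) interaction(comp, block, drop = TRUE) else factor(comp)
    groups <- split(seq_len(prod(shape)), cell)

    # fixed per-(compartment, block) draws: orientation choice, random
    # direction, phase -- drawn for every group in deterministic order
    ng <- length(groups)
    u_mix <- stats::runif(ng)
    rand_dir <- runif_sphere(ng)
    phase <- stats::runif(ng, 0, 2 * pi)

    edge_axes <- if (!is.null(part)) {
      lapply(seq_len(nrow(graph$edges)), function(j) {
        unitize(edge_vector(graph, graph$edges$u[j], graph$edges$v[j]))
      })
    } else list()

    block_dir <- matrix(NA_real_, nrow = ng, ncol = 3)
    vals <- numeric(prod(shape))
    for (g in seq_len(ng)) {
      idx <- groups[[g]]
      cmp <- comp[idx[1]]
      axis <- if (length(edge_axes) && cmp >= 1L) edge_axes[[cmp]] else c(1, 0, 0)
      k <- switch(spec$fiber_mode,
        perpendicular = unitize(perpendicular_to(axis)),
        parallel = axis,
        uniform3d = rand_dir[g, ],
        mixture = if (u_mix[g] < spec$mixture_fraction) {
          unitize(perpendicular_to(axis))
        } else rand_dir[g, ]
      )
      block_dir[g, ] <- k
      proj <- co[idx, , drop = FALSE] %*% k
      vals[idx] <- spec$stripe_amplitude *
        sin(2 * pi * proj / spec$stripe_wavelength_um + phase[g])
    }
    a <- a + array(vals, shape)
    if (spec$ramp_gradient != 0) {
      a <- a + array(spec$ramp_gradient * co[, 2], shape)
    }
    if (spec$noise_sd > 0) {
      a <- a + array(stats::rnorm(length(a), 0, spec$noise_sd), shape)
    }
    a <- a - min(a) # keep intensities non-negative without changing gradients
    out <- image_stack(a, sp, "collagen")
    attr(out, "truth") <- list(
      fiber_mode = spec$fiber_mode,
      mixture_fraction = spec$mixture_fraction,
      block_table = tibble::tibble(
        group = seq_len(ng),
        kz = block_dir[, 1], ky = block_dir[, 2], kx = block_dir[, 3],
        perpendicular = if (spec$fiber_mode == "mixture") {
          u_mix < spec$mixture_fraction
        } else rep(spec$fiber_mode == "perpendicular", ng)
      )
    )
    out
  })
}

#' Generate a synthetic remodeling time course
#'
#' Produces one paired (nuclei, collagen) sample per time point with
#' fixed planted centroids. `alignment_profile` sets the mixture fraction
#' `f` of perpendicular-gradient blocks at each time point (controls the
#' measured CAI); `cancellation_profile` (in `[0, 1]`) scales down the
#' planted ramp, `ramp = ramp_max * (1 - cancellation)`, so increasing
#' cancellation means increasingly balanced pull forces and a decreasing
#' GDL. Stripe orientation draws are shared across time points, so
#' metric changes are driven by the profiles alone.
#'
#' @param n_timepoints number of time points.
#' @param alignment_profile numeric vector of length `n_timepoints`,
#'   values in `[0, 1]`.
#' @param cancellation_profile numeric vector of length `n_timepoints`,
#'   values in `[0, 1]`.
#' @param base_spec a [synthetic_spec()] used as the template; its
#'   `fiber_mode` is forced to `"mixture"`.
#' @param ramp_max ramp slope (intensity per um) at zero cancellation.
#' @return List of per-timepoint entries: `nuclei` and `collagen` stacks,
#'   `truth` (tibble `timepoint`, `f`, `cancellation`, `ramp_gradient`),
#'   and the shared centroid table.
#' @export
generate_timecourse <- function(n_timepoints,
                                alignment_profile,
                                cancellation_profile,
                                base_spec = synthetic_spec(),
                                ramp_max = 150) {
  stopifnot(length(alignment_profile) == n_timepoints,
            length(cancellation_profile) == n_timepoints,
            all(alignment_profile >= 0 & alignment_profile <= 1),
            all(cancellation_profile >= 0 & cancellation_profile <= 1))
  spec0 <- base_spec
  spec0$fiber_mode <- "mixture"
  if (is.null(spec0$centroids)) {
    spec0$centroids <- withr::with_seed(spec0$seed, draw_centroids(spec0))
  }
  nuc <- generate_nuclei_channel(spec0)
  graph <- build_cell_graph(nuc$truth, link_threshold_um = 55)
  purrr::map(seq_len(n_timepoints), function(t) {
    spec_t <- spec0
    spec_t$mixture_fraction <- alignment_profile[t]
    spec_t$ramp_gradient <- ramp_max * (1 - cancellation_profile[t])
    col <- generate_collagen_channel(spec_t, graph)
    list(
      nuclei = nuc$stack,
      collagen = col,
      centroids = nuc$truth,
      truth = tibble::tibble(
        timepoint = t,
        f = alignment_profile[t],
        cancellation = cancellation_profile[t],
        ramp_gradient = spec_t$ramp_gradient
      )
    )
  })
}
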