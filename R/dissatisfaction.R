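#' Net gradient ("net pull") vector of a cell
#'
#' Vector sum of all gradient vectors inside the node's Voronoi
#' compartment. Larger norms indicate stronger directional interaction
#' between the cell and the surrounding collagen. An empty compartment
#' yields the zero vector.
#'
#' @param node_id a node id of the graph that seeded `partition`.
#' @param partition node-mode `partition_volume`.
#' @param field `gradient_field` over the same grid.
#' @return A `net_force`: list with `node`, `vector` (3-vector, intensity
#'   per um, axis order depth/row/col), `n_voxels`, and the diagnostic
#'   `magnitude_sum` (sum of gradient magnitudes in the compartment).
#' @export
net_gradient_vector <- function(node_id, partition, field) {
  stopifnot(inherits(partition, "partition_volume"), partition$mode == "node",
            inherits(field, "gradient_field"))
  lab <- node_label(partition, node_id)
  if (is.na(lab)) stop("node ", node_id, " absent from partition", call. = FALSE)
  idx <- compartment_indices(partition, lab)
  v <- c(sum(field$gz[idx]), sum(field$gy[idx]), sum(field$gx[idx]))
  structure(
    list(node = node_id, vector = v, n_voxels = length(idx),
         magnitude_sum = sum(field$magnitude[idx])),
    class = "net_force"
  )
}

# deterministic unit-free perpendicular: cross the vector with the canonical
# axis least aligned with it (smallest |cosine|)
perpendicular_to <- function(e) {
  axes <- diag(3)
  cosines <- abs(as.vector(axes %*% e)) / sqrt(sum(e^2))
  a <- axes[, which.min(cosines)]
  cross3(e, a)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Complete a node's incident edge vectors to a spanning basis
#'
#' The projection of a net pull vector onto cell-graph edges needs the
#' edge vectors to span 3-space. Nodes of degree >= 3 are used as-is
#' (possibly underdetermined). A degree-2 node gains one hypothetical
#' edge, the cross product of its two real edges; a degree-1 node gains a
#' deterministic perpendicular to its single edge and then the cross
#' product of the pair, giving three mutually orthogonal columns. Every
#' hypothetical edge is rescaled to the mean real-edge norm so the system
#' stays well-conditioned; hypothetical columns are flagged and their
#' solved weights never enter CDL/GDL.
#'
#' @param edge_vectors 3 x k matrix whose columns are the edge vectors
#'   emanating from the node (um), k >= 1.
#' @param edge_keys optional character labels for the real columns.
#' @return An `edge_basis`: list with matrix `E` (3 x m), logical
#'   `hypothetical` of length m, and `keys` (hypothetical columns get
#'   `NA`).
#' @export
complete_edge_basis <- function(edge_vectors, edge_keys = NULL) {
  E <- as.matrix(edge_vectors)
  stopifnot(nrow(E) == 3L, ncol(E) >= 1L, all(is.finite(E)))
  if (any(colSums(E^2) == 0)) stop("zero-length edge vector", call. = FALSE)
  k <- ncol(E)
  keys <- edge_keys %||% as.character(seq_len(k))
  stopifnot(length(keys) == k)
  scale_norm <- mean(sqrt(colSums(E^2)))
  rescale <- function(v) v / sqrt(sum(v^2)) * scale_norm

  if (k >= 3L) {
    hyp <- rep(FALSE, k)
  } else if (k == 2L) {
    cp <- cross3(E[, 1], E[, 2])
    if (sum(cp^2) < 1e-12 * sum(E[, 1]^2) * sum(E[, 2]^2)) {
      # parallel real edges: treat like degree 1 on the first edge
      h1 <- rescale(perpendicular_to(E[, 1]))
      h2 <- rescale(cross3(E[, 1], h1))
      E <- cbind(E, h1, h2)
      hyp <- c(FALSE, FALSE, TRUE, TRUE)
      keys <- c(keys, NA, NA)
    } else {
      E <- cbind(E, rescale(cp))
      hyp <- c(FALSE, FALSE, TRUE)
      keys <- c(keys, NA)
    }
  } else { # k == 1
    h1 <- rescale(perpendicular_to(E[, 1]))
    h2 <- rescale(cross3(E[, 1], h1))
    E <- cbind(E, h1, h2)
    hyp <- c(FALSE, TRUE, TRUE)
    keys <- c(keys, NA, NA)
  }
  dimnames(E) <- NULL
  structure(list(E = E, hypothetical = hyp, keys = keys), class = "edge_basis")
}

#' Minimum-norm projection of a net force onto edge vectors
#'
#' Solves `E w = F` for the projection weights `w`. With exactly three
#' independent columns the solution is the unique linear solve; with more
#' than three columns the system is underdetermined and the
#' minimum-Euclidean-norm solution `w = t(E) solve(E t(E)) F` is
#' returned. Numerically rank-deficient systems fall back to the
#' Moore-Penrose pseudoinverse with a warning.
#'
#' @param basis an `edge_basis`, or a plain 3 x k matrix (k >= 3).
#' @param force numeric 3-vector (the net gradient vector).
#' @return A `projection_weights`: list with `weights`, `hypothetical`
#'   flags, `keys`, `residual` (norm of `E w - F`), and `force`.
#' @export
minimum_norm_projection <- function(basis, force) {
  if (!inherits(basis, "edge_basis")) {
    E <- as.matrix(basis)
    basis <- structure(list(E = E, hypothetical = rep(FALSE, ncol(E)),
                            keys = as.character(seq_len(ncol(E)))),
                       class = "edge_basis")
  }
  E <- basis$E
  force <- as.numeric(force)
  stopifnot(nrow(E) == 3L, ncol(E) >= 3L, length(force) == 3L, all(is.finite(force)))
  w <- NULL
  if (ncol(E) == 3L) {
    w <- tryCatch(solve(E, force), error = function(e) NULL)
  } else {
    G <- E %*% t(E)
    w <- tryCatch(as.vector(t(E) %*% solve(G, force)), error = function(e) NULL)
  }
  if (is.null(w)) {
    warning("rank-deficient edge system; using pseudoinverse solution")
    w <- as.vector(MASS::ginv(E) %*% force)
  }
  w <- as.vector(w)
  res <- sqrt(sum((as.vector(E %*% w) - force)^2))
  nf <- sqrt(sum(force^2))
  if (nf > 0 && res > 1e-6 * nf) {
    warning(sprintf("projection residual %.3g exceeds tolerance", res / nf))
  }
  structure(
    list(weights = w, hypothetical = basis$hypothetical, keys = basis$keys,
         residual = res, force = force),
    class = "projection_weights"
  )
}

edge_key <- function(u, v) paste0(pmin(u, v), "-", pmax(u, v))

#' Project every cell's net pull onto its incident edges
#'
#' Convenience driver: for each node of positive degree, sums the
#' gradients of its Voronoi compartment, completes the incident edge
#' vectors to a spanning basis, and solves for the minimum-norm projection
#' weights. Degree-0 nodes are skipped (they have no edges to weight).
#'
#' @param graph a `cell_graph`.
#' @param partition node-mode `partition_volume`.
#' @param field `gradient_field`.
#' @return Named list (by node id) of entries `force` (`net_force`) and
#'   `projection` (`projection_weights` whose `keys` are `"u-v"` edge
#'   keys).
#' @export
node_projections <- function(graph, partition, field) {
  deg <- node_degrees(graph)
  out <- list()
  for (i in seq_len(nrow(graph$nodes))) {
    if (deg[i] == 0L) next
    id <- graph$nodes$id[i]
    inc <- graph$edges[graph$edges$u == id | graph$edges$v == id, , drop = FALSE]
    vecs <- vapply(seq_len(nrow(inc)), function(j) {
      edge_vector(graph, inc$u[j], inc$v[j], origin_node = id)
    }, numeric(3))
    keys <- edge_key(inc$u, inc$v)
    nf <- net_gradient_vector(id, partition, field)
    basis <- complete_edge_basis(matrix(vecs, nrow = 3), keys)
    out[[as.character(id)]] <- list(
      force = nf,
      projection = minimum_norm_projection(basis, nf$vector)
    )
  }
  out
}

#' Cell Dissatisfaction Level of every edge
#'
#' Each endpoint of an edge contributes a force along the shared edge:
#' its solved projection coefficient times the unit vector of its
#' outgoing edge direction. The CDL of the edge is the Euclidean norm of
#' the vector sum of the two contributions, so equal-magnitude
#' coefficients pulling toward each other cancel to 0 (local
#' homeostasis). Weights on hypothetical basis columns belong to no real
#' edge and are discarded. Nodes without a projection contribute zero
#' force.
#'
#' @param graph a `cell_graph`.
#' @param projections output of [node_projections()].
#' @return Tibble `u`, `v`, `cdl` (one row per edge of `graph`).
#' @export
compute_cdl <- function(graph, projections) {
  e <- graph$edges
  if (!nrow(e)) return(tibble::tibble(u = integer(), v = integer(), cdl = numeric()))
  cdl <- numeric(nrow(e))
  for (j in seq_len(nrow(e))) {
    u <- e$u[j]; v <- e$v[j]
    key <- edge_key(u, v)
    total <- c(0, 0, 0)
    for (end in c(u, v)) {
      pr <- projections[[as.character(end)]]
      if (is.null(pr)) next
      pos <- which(!is.na(pr$projection$keys) & pr$projection$keys == key &
                     !pr$projection$hypothetical)
      if (!length(pos)) next
      dir <- edge_vector(graph, u, v, origin_node = end)
      total <- total + pr$projection$weights[pos[1]] * dir / sqrt(sum(dir^2))
    }
    cdl[j] <- sqrt(sum(total^2))
  }
  tibble::tibble(u = e$u, v = e$v, cdl = cdl)
}

#' Global Dissatisfaction Level
#'
#' Sum of all edge CDLs normalized to image size. By default "image size"
#' is the total voxel count; set `physical = TRUE` to divide by the
#' physical volume in cubic um instead.
#'
#' @param cdl tibble from [compute_cdl()] (or numeric vector of CDLs).
#' @param image_voxels total voxel count of the analysed stack.
#' @param spacing_um voxel spacing, only used when `physical = TRUE`.
#' @param physical divide by physical volume instead of voxel count.
#' @return Scalar GDL. 0, with a warning, for an empty edge set.
#' @export
compute_gdl <- function(cdl, image_voxels, spacing_um = c(1, 1, 1),
                        physical = FALSE) {
  vals <- if (is.data.frame(cdl)) cdl$cdl else as.numeric(cdl)
  stopifnot(all(is.finite(vals)), image_voxels > 0)
  if (!length(vals)) {
    warning("empty edge set; GDL = 0")
    return(0)
  }
  denom <- if (physical) image_voxels * prod(spacing_um) else image_voxels
  sum(vals) / denom
}
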