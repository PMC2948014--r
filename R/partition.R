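#' Discrete Voronoi partition of the voxel grid
#'
#' Assigns every voxel of a grid to the nearest seed in physical (um)
#' space, honouring anisotropic spacing. Seeds are either the cell-graph
#' nodes (`mode = "node"`) or the cell-graph edge midpoints
#' (`mode = "edge_midpoint"`), the latter guaranteeing that each edge is
#' encapsulated in exactly one compartment. Equidistant voxels go to the
#' lowest seed label, which makes the assignment deterministic.
#'
#' @param shape integer 3-vector, grid dimensions (depth, row, col).
#' @param spacing_um voxel spacing in um, (depth, row, col).
#' @param graph a `cell_graph`.
#' @param mode `"node"` or `"edge_midpoint"`.
#' @return A `partition_volume`: list with `labels` (integer array of
#'   `shape`; -1 where no seeds exist), `seed_table` (tibble `label`,
#'   `kind`, `id`, `u`, `v`, `z_um`, `y_um`, `x_um`), `mode`,
#'   `spacing_um`.
#' @examples
#' g <- build_cell_graph(rbind(c(0, 0, 0), c(0, 0, 100)), link_threshold_um = 150)
#' p <- voronoi_assign(c(1, 1, 101), c(1, 1, 1), g, "node")
#' p$labels[1, 1, c(1, 101)] # 1 2
#' @export
voronoi_assign <- function(shape, spacing_um, graph,
                           mode = c("node", "edge_midpoint")) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  spacing_um <- as.numeric(spacing_um)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing_um) == 3L, all(spacing_um > 0),
            inherits(graph, "cell_graph"))

  if (mode == "node") {
    seeds <- as.matrix(graph$nodes[, c("z_um", "y_um", "x_um")])
    seed_table <- tibble::tibble(
      label = seq_len(nrow(graph$nodes)), kind = "node", id = graph$nodes$id,
      u = NA_integer_, v = NA_integer_,
      z_um = seeds[, 1], y_um = seeds[, 2], x_um = seeds[, 3]
    )
  } else {
    seeds <- edge_midpoints(graph)
    seed_table <- tibble::tibble(
      label = seq_len(nrow(graph$edges)), kind = "edge", id = NA_integer_,
      u = graph$edges$u, v = graph$edges$v,
      z_um = seeds[, 1], y_um = seeds[, 2], x_um = seeds[, 3]
    )
  }

  labels <- array(-1L, shape)
  if (nrow(seed_table) == 0L) {
    warning("no seeds in mode '", mode, "'; all voxels unassigned (-1)")
  } else {
    c1 <- axis_coords(shape[1], spacing_um[1])
    c2 <- axis_coords(shape[2], spacing_um[2])
    c3 <- axis_coords(shape[3], spacing_um[3])
    best <- array(Inf, shape)
    lab <- array(0L, shape)
    n12 <- shape[1] * shape[2]
    for (s in seq_len(nrow(seeds))) {
      # separable squared distance, voxel order column-major (depth fastest)
      d2 <- outer(
        outer((c1 - seeds[s, 1])^2, (c2 - seeds[s, 2])^2, "+"),
        (c3 - seeds[s, 3])^2, "+"
      )
      upd <- d2 < best # strict: earlier (lower) label wins ties
      best[upd] <- d2[upd]
      lab[upd] <- s
    }
    labels <- lab
  }
  structure(
    list(labels = labels, seed_table = seed_table, mode = mode,
         spacing_um = spacing_um),
    class = "partition_volume"
  )
}

#' @export
print.partition_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<partition_volume> %d x %d x %d voxels, %d %s seed(s)\n",
              d[1], d[2], d[3], nrow(x$seed_table), x$mode))
  invisible(x)
}

# linear voxel indices of one compartment
compartment_indices <- function(partition, label) {
  which(partition$labels == label)
}

# label of the compartment owned by a node / an edge, or NA
node_label <- function(partition, id) {
  stopifnot(partition$mode == "node")
  partition$seed_table$label[match(id, partition$seed_table$id)]
}

edge_label <- function(partition, u, v) {
  stopifnot(partition$mode == "edge_midpoint")
  st <- partition$seed_table
  hit <- (st$u == u & st$v == v) | (st$u == v & st$v == u)
  if (!any(hit)) return(NA_integer_)
  st$label[which(hit)[1]]
}

#' Compartment sizes of a partition
#'
#' @param partition a `partition_volume`.
#' @return Tibble `label`, `kind`, `n_voxels` (seeds owning zero voxels
#'   are included with 0).
#' @export
compartment_sizes <- function(partition) {
  stopifnot(inherits(partition, "partition_volume"))
  st <- partition$seed_table
  cnt <- tabulate(partition$labels[partition$labels > 0L], nbins = max(st$label, 0L))
  tibble::tibble(label = st$label, kind = st$kind,
                 n_voxels = as.integer(cnt[st$label]))
}
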