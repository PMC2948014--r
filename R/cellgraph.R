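#' Euclidean distance between two points in micrometres
#'
#' @param a,b numeric 3-vectors of physical coordinates (um).
#' @return Non-negative scalar distance in um.
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

# Coerce a nucleus table / matrix into an id + 3-column (z,y,x um) coordinate
# pair. Accepts the tibble produced by segment_nuclei() (columns id, x_um,
# y_um, z_um) or a plain matrix with columns in (depth,row,col) order.
node_table <- function(nuclei) {
  if (is.matrix(nuclei)) {
    stopifnot(ncol(nuclei) == 3L)
    return(tibble::tibble(
      id = seq_len(nrow(nuclei)),
      z_um = nuclei[, 1], y_um = nuclei[, 2], x_um = nuclei[, 3]
    ))
  }
  stopifnot(is.data.frame(nuclei), all(c("id", "x_um", "y_um", "z_um") %in% names(nuclei)))
  tibble::tibble(
    id = nuclei$id,
    z_um = nuclei$z_um, y_um = nuclei$y_um, x_um = nuclei$x_um
  )
}

new_cell_graph <- function(nodes, edges, link_threshold_um) {
  structure(
    list(nodes = nodes, edges = edges, link_threshold_um = link_threshold_um),
    class = "cell_graph"
  )
}

#' Build a 3D cell-graph from nucleus centroids
#'
#' One vertex per nucleus; an undirected edge joins two nuclei whenever
#' their Euclidean distance is positive and at most `link_threshold_um`.
#' The default threshold of 55 um corresponds to roughly two rounded cell
#' diameters. Disconnected graphs and degree-0 nodes are allowed.
#'
#' @param nuclei a nucleus table as returned by [segment_nuclei()]
#'   (columns `id`, `x_um`, `y_um`, `z_um`), or an n x 3 coordinate matrix
#'   in (depth, row, col) um.
#' @param link_threshold_um maximum link length in um.
#' @return A `cell_graph`: list with `nodes` (tibble `id`, `z_um`, `y_um`,
#'   `x_um`), `edges` (tibble `u`, `v`, `length_um`, with `u < v` by node
#'   order), and `link_threshold_um`.
#' @examples
#' pts <- rbind(c(0, 0, 0), c(0, 0, 50), c(0, 0, 120))
#' g <- build_cell_graph(pts, 55)
#' nrow(g$edges) # 1
#' @export
build_cell_graph <- function(nuclei, link_threshold_um = 55) {
  nodes <- node_table(nuclei)
  if (nrow(nodes) < 1L) stop("need at least one nucleus", call. = FALSE)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  stopifnot(is.numeric(link_threshold_um), link_threshold_um >= 0)

  co <- as.matrix(nodes[, c("z_um", "y_um", "x_um")])
  n <- nrow(co)
  if (n >= 2L) {
    dmat <- as.matrix(stats::dist(co))
    pair <- which(upper.tri(dmat), arr.ind = TRUE)
    d <- dmat[pair]
    if (any(d == 0)) {
      warning("coincident centroids with distinct ids; no edge added between them")
    }
    keep <- d > 0 & d <= link_threshold_um
    edges <- tibble::tibble(
      u = nodes$id[pair[keep, 1]],
      v = nodes$id[pair[keep, 2]],
      length_um = d[keep]
    )
    edges <- dplyr::arrange(edges, .data$u, .data$v)
  } else {
    edges <- tibble::tibble(u = integer(), v = integer(), length_um = numeric())
  }
  new_cell_graph(nodes, edges, link_threshold_um)
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d edges (link threshold %.3g um)\n",
              nrow(x$nodes), nrow(x$edges), x$link_threshold_um))
  if (nrow(x$edges) && "weight" %in% names(x$edges)) cat("  edges carry weights\n")
  invisible(x)
}

# coordinate (z,y,x um) of one node
node_coord <- function(graph, id) {
  i <- match(id, graph$nodes$id)
  if (is.na(i)) stop("node ", id, " not in graph", call. = FALSE)
  c(graph$nodes$z_um[i], graph$nodes$y_um[i], graph$nodes$x_um[i])
}

has_edge <- function(graph, u, v) {
  any((graph$edges$u == u & graph$edges$v == v) |
      (graph$edges$u == v & graph$edges$v == u))
}

#' Edge vector of a cell-graph edge, oriented away from a node
#'
#' Returns the 3-vector (um, axis order depth/row/col) from `origin_node`
#' to the other endpoint of edge `(u, v)`. Taking the vector from the two
#' ends gives negatives of each other.
#'
#' @param graph a `cell_graph`.
#' @param u,v endpoints of an existing edge.
#' @param origin_node which endpoint to anchor at (default `u`).
#' @return Numeric 3-vector in um.
#' @export
edge_vector <- function(graph, u, v, origin_node = u) {
  if (!has_edge(graph, u, v)) {
    stop(sprintf("edge (%s, %s) not in graph", u, v), call. = FALSE)
  }
  if (!origin_node %in% c(u, v)) {
    stop("`origin_node` must be one of the edge endpoints", call. = FALSE)
  }
  other <- if (origin_node == u) v else u
  node_coord(graph, other) - node_coord(graph, origin_node)
}

# midpoints of all edges: matrix n_edges x 3 (z,y,x um)
edge_midpoints <- function(graph) {
  if (nrow(graph$edges) == 0L) {
    return(matrix(numeric(), ncol = 3))
  }
  a <- t(vapply(graph$edges$u, function(id) node_coord(graph, id), numeric(3)))
  b <- t(vapply(graph$edges$v, function(id) node_coord(graph, id), numeric(3)))
  (a + b) / 2
}

#' Attach per-edge weights to a cell-graph
#'
#' @param graph a `cell_graph`.
#' @param weights tibble/data frame with columns `u`, `v` and one value
#'   column (e.g. `cai` or `cdl`), or a numeric vector ordered like
#'   `graph$edges`.
#' @param column name of the value column when `weights` is a data frame.
#' @return The graph with a `weight` column on its edge table.
#' @export
set_edge_weights <- function(graph, weights, column = NULL) {
  stopifnot(inherits(graph, "cell_graph"))
  if (is.numeric(weights)) {
    stopifnot(length(weights) == nrow(graph$edges))
    graph$edges$weight <- as.numeric(weights)
    return(graph)
  }
  stopifnot(is.data.frame(weights), all(c("u", "v") %in% names(weights)))
  if (is.null(column)) {
    column <- setdiff(names(weights), c("u", "v"))[1]
  }
  key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  m <- match(key(graph$edges$u, graph$edges$v), key(weights$u, weights$v))
  graph$edges$weight <- weights[[column]][m]
  graph
}

#' Highlight strongly aligned edges
#'
#' Returns the subgraph whose edges have weight strictly greater than
#' `threshold`; all nodes are retained. With CAI weights and the default
#' threshold of 0.6 this picks out regions of enhanced collagen
#' remodeling; with CDL weights it locates unbalanced pull forces.
#'
#' @param graph a `cell_graph`.
#' @param weights per-edge weights (see [set_edge_weights()]); omit if the
#'   graph already carries a `weight` column.
#' @param threshold keep edges with `weight > threshold`. Default 0.6.
#' @return A `cell_graph` subgraph.
#' @export
highlight_edges <- function(graph, weights = NULL, threshold = 0.6) {
  stopifnot(inherits(graph, "cell_graph"))
  if (!is.null(weights)) graph <- set_edge_weights(graph, weights)
  if (nrow(graph$edges) && !"weight" %in% names(graph$edges)) {
    stop("graph edges carry no weights; supply `weights`", call. = FALSE)
  }
  e <- graph$edges
  if (nrow(e)) {
    if (anyNA(e$weight)) {
      warning(sum(is.na(e$weight)), " edge(s) lack a weight and are excluded")
    }
    e <- e[!is.na(e$weight) & e$weight > threshold, , drop = FALSE]
  }
  new_cell_graph(graph$nodes, e, graph$link_threshold_um)
}

#' Alias of [highlight_edges()] for dissatisfaction weights
#'
#' Keeps the edges whose Cell Dissatisfaction Level exceeds `threshold`,
#' localizing microenvironments where remodeling forces remain unbalanced.
#'
#' @inheritParams highlight_edges
#' @param cdl tibble with columns `u`, `v`, `cdl` as from [compute_cdl()].
#' @return A `cell_graph` subgraph.
#' @export
filter_cdl_edges <- function(graph, cdl, threshold) {
  highlight_edges(graph, weights = cdl, threshold = threshold)
}

#' Sweep the link threshold and summarise graph topology
#'
#' Re-builds the cell-graph over a range of link thresholds (the published
#' parametric search spans 10-180 um) and reports edge counts and degrees.
#'
#' @param nuclei nucleus table or coordinate matrix (see
#'   [build_cell_graph()]).
#' @param thresholds_um numeric vector of thresholds to evaluate.
#' @return Tibble with columns `threshold_um`, `n_edges`, `mean_degree`,
#'   `n_isolated`, `n_components`.
#' @export
sweep_link_threshold <- function(nuclei, thresholds_um = seq(10, 180, by = 10)) {
  nodes <- node_table(nuclei)
  purrr::map_dfr(sort(thresholds_um), function(th) {
    g <- build_cell_graph(nodes_to_nuclei(nodes), th)
    deg <- node_degrees(g)
    comp <- if (nrow(g$nodes)) {
      ig <- as_igraph(g)
      igraph::count_components(ig)
    } else 0L
    tibble::tibble(
      threshold_um = th,
      n_edges = nrow(g$edges),
      mean_degree = mean(deg),
      n_isolated = sum(deg == 0),
      n_components = comp
    )
  })
}

# internal: nodes tibble (z,y,x) -> the user-facing column layout
nodes_to_nuclei <- function(nodes) {
  tibble::tibble(id = nodes$id, x_um = nodes$x_um, y_um = nodes$y_um,
                 z_um = nodes$z_um)
}

node_degrees <- function(graph) {
  tab <- table(factor(c(graph$edges$u, graph$edges$v), levels = graph$nodes$id))
  as.integer(tab)
}

# igraph view of a cell_graph (nodes keep their ids as names)
as_igraph <- function(graph) {
  ig <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = as.character(graph$nodes$id))
  ig <- igraph::set_vertex_attr(ig, "z", value = graph$nodes$z_um)
  ig <- igraph::set_vertex_attr(ig, "y", value = graph$nodes$y_um)
  ig <- igraph::set_vertex_attr(ig, "x", value = graph$nodes$x_um)
  if (nrow(graph$edges)) {
    el <- rbind(match(graph$edges$u, graph$nodes$id),
                match(graph$edges$v, graph$nodes$id))
    ig <- igraph::add_edges(ig, as.vector(el))
    ig <- igraph::set_edge_attr(ig, "length_um", value = graph$edges$length_um)
    if ("weight" %in% names(graph$edges)) {
      ig <- igraph::set_edge_attr(ig, "weight", value = graph$edges$weight)
    }
  }
  ig
}
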