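#' Serialize a (weighted) cell-graph to GraphML
#'
#' Nodes carry `name` (the nucleus id) and `x`/`y`/`z` coordinates in um;
#' edges carry `length_um` and, when present, `weight` (CAI or CDL).
#' Reading the file back with [read_weighted_graph()] reproduces topology
#' exactly and numeric attributes to better than 1e-9.
#'
#' @param graph a `cell_graph`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_weighted_graph <- function(graph, path) {
  stopifnot(inherits(graph, "cell_graph"))
  if ("weight" %in% names(graph$edges) && nrow(graph$edges) &&
      !all(is.finite(graph$edges$weight))) {
    stop("edge weights must be finite", call. = FALSE)
  }
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML cell-graph written by [write_weighted_graph()]
#'
#' @param path path to a `.graphml` file.
#' @param link_threshold_um threshold to record on the result (GraphML does
#'   not store it); defaults to `NA`.
#' @return A `cell_graph`.
#' @export
read_weighted_graph <- function(path, link_threshold_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ig <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::vertex_attr(ig, "name")
  ids <- if (all(grepl("^-?[0-9]+$", ids))) as.integer(ids) else ids
  nodes <- tibble::tibble(
    id = ids,
    z_um = igraph::vertex_attr(ig, "z"),
    y_um = igraph::vertex_attr(ig, "y"),
    x_um = igraph::vertex_attr(ig, "x")
  )
  el <- igraph::as_edgelist(ig, names = FALSE)
  edges <- tibble::tibble(
    u = nodes$id[el[, 1]],
    v = nodes$id[el[, 2]],
    length_um = igraph::edge_attr(ig, "length_um") %||% rep(NA_real_, nrow(el))
  )
  w <- igraph::edge_attr(ig, "weight")
  if (!is.null(w)) edges$weight <- w
  # normalise orientation u < v like build_cell_graph()
  if (nrow(edges)) {
    flip <- edges$u > edges$v
    tmp <- edges$u[flip]; edges$u[flip] <- edges$v[flip]; edges$v[flip] <- tmp
    edges <- dplyr::arrange(edges, .data$u, .data$v)
  }
  new_cell_graph(nodes, edges, link_threshold_um)
}

#' Write the edge list of a cell-graph as CSV
#'
#' Columns: `u`, `v`, `length_um` and `weight` (if present).
#'
#' @param graph a `cell_graph`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_edge_csv <- function(graph, path) {
  stopifnot(inherits(graph, "cell_graph"))
  utils::write.csv(as.data.frame(graph$edges), path, row.names = FALSE)
  invisible(path)
}

#' Write a nucleus centroid table as CSV
#'
#' Columns: `id`, `x_um`, `y_um`, `z_um`, `voxels`.
#'
#' @param nuclei tibble from [segment_nuclei()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_centroid_csv <- function(nuclei, path) {
  utils::write.csv(as.data.frame(nuclei), path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report (JSON scalars + CSV histograms)
#'
#' Scalar entries of `report` go into one JSON object at `path`. Entries
#' that are angle distributions (class `angle_distribution`) or data frames
#' are written as sibling CSV files named `<stem>_<entry>.csv`; histogram
#' CSVs have columns `bin_center_deg`, `weight`, `pdf`.
#'
#' @param report named list of finite scalars, `angle_distribution`
#'   objects and/or data frames.
#' @param path output `.json` path for the scalar part.
#' @return Character vector of all files written, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(is.list(report), length(names(report)) == length(report))
  stem <- sub("\\.json$", "", path, ignore.case = TRUE)
  scalars <- list()
  written <- character()
  for (k in names(report)) {
    x <- report[[k]]
    if (inherits(x, "angle_distribution")) x <- tidy(x)
    if (is.data.frame(x)) {
      f <- paste0(stem, "_", k, ".csv")
      utils::write.csv(as.data.frame(x), f, row.names = FALSE)
      written <- c(written, f)
    } else if (is.numeric(x) && length(x) == 1L) {
      if (!is.finite(x)) stop("metric '", k, "' is not finite", call. = FALSE)
      scalars[[k]] <- x
    } else {
      stop("metric '", k, "' must be a finite scalar, data frame, or ",
           "angle_distribution", call. = FALSE)
    }
  }
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, written))
}

#' Export a partition label volume as multi-page TIFF
#'
#' Labels are written as 16-bit integers; unassigned voxels (-1) become 0.
#'
#' @param partition a `partition_volume` from [voronoi_assign()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(partition, path) {
  stopifnot(inherits(partition, "partition_volume"))
  lab <- partition$labels
  lab[lab < 0] <- 0L
  write_stack(image_stack(lab, partition$spacing_um, "labels"), path)
}
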