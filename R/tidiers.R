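#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an angle distribution into a bin table
#'
#' @param x an `angle_distribution`.
#' @param ... unused.
#' @return Tibble `bin_center_deg`, `weight`, `pdf`.
#' @export
tidy.angle_distribution <- function(x, ...) {
  tibble::tibble(bin_center_deg = x$bin_center, weight = x$weight, pdf = x$pdf)
}

#' One-row summary of an angle distribution
#' @param x an `angle_distribution`.
#' @param ... unused.
#' @return Tibble with `n_values`, `total_weight`, `peak_deg` (bin centre
#'   of maximal weight), `usable`.
#' @export
glance.angle_distribution <- function(x, ...) {
  tibble::tibble(
    n_values = x$n_values,
    total_weight = x$total_weight,
    peak_deg = if (x$usable) x$bin_center[which.max(x$weight)] else NA_real_,
    usable = x$usable
  )
}

#' Tidy a cell-graph into its edge table
#' @param x a `cell_graph`.
#' @param ... unused.
#' @return The edge tibble (`u`, `v`, `length_um`, optional `weight`).
#' @export
tidy.cell_graph <- function(x, ...) x$edges

#' One-row topology summary of a cell-graph
#' @param x a `cell_graph`.
#' @param ... unused.
#' @export
glance.cell_graph <- function(x, ...) {
  deg <- node_degrees(x)
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    mean_degree = mean(deg), n_isolated = sum(deg == 0),
    link_threshold_um = x$link_threshold_um
  )
}

#' One-row summary of a CAI result
#' @param x a `cai_result`.
#' @param ... unused.
#' @export
glance.cai_result <- function(x, ...) {
  tibble::tibble(cai = x$cai, lo_deg = x$lo_deg, hi_deg = x$hi_deg,
                 n_voxels_used = x$n_voxels_used)
}

#' One-row summary of a KS comparison
#' @param x a `ks_result`.
#' @param ... unused.
#' @export
glance.ks_result <- function(x, ...) {
  tibble::tibble(D = x$D, p_value = x$p_value,
                 reject_at_5pct = x$reject_at_5pct,
                 n_eff_1 = x$n_eff_1, n_eff_2 = x$n_eff_2)
}

#' Tidy a phase assignment into its sample table
#' @param x a `phase_assignment`.
#' @param ... unused.
#' @export
tidy.phase_assignment <- function(x, ...) x$assignments

#' One-row summary of an Otsu split
#' @param x an `otsu_split`.
#' @param ... unused.
#' @export
glance.otsu_split <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, p1 = x$p1, p2 = x$p2,
                 var1 = x$var1, var2 = x$var2,
                 intra_class_variance = x$intra_class_variance)
}
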