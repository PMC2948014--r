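#' Run configuration for the remodeling pipeline
#'
#' Bundles every tunable parameter of the analysis. Defaults follow the
#' published protocol for mesenchymal stem cells in type I collagen gels:
#' a 55 um link threshold (about two rounded cell diameters), the
#' `[60, 120]` degree window for the Collagen Alignment Index, and a 0.6
#' CAI highlight threshold.
#'
#' @param link_threshold_um maximum Euclidean distance (um) between two
#'   nuclei for a cell-graph edge. Default 55.
#' @param cai_lo_deg,cai_hi_deg angle window (degrees) whose probability
#'   mass defines the CAI. Defaults 60 and 120.
#' @param highlight_cai CAI threshold above which edges are highlighted.
#' @param bins number of uniform histogram bins over `[0, 180]` degrees.
#' @param k_clusters number of k-means phase clusters.
#' @param svd_dims number of singular directions kept before clustering.
#' @param connectivity voxel connectivity for nucleus labeling, 6 or 26.
#' @param min_size smallest connected component (voxels) kept as a nucleus.
#' @param seed integer seed controlling all randomized steps.
#'
#' @return A validated list of class `run_config`.
#' @examples
#' cfg <- run_config(link_threshold_um = 60)
#' cfg$cai_lo_deg
#' @export
run_config <- function(link_threshold_um = 55,
                       cai_lo_deg = 60,
                       cai_hi_deg = 120,
                       highlight_cai = 0.6,
                       bins = 180L,
                       k_clusters = 3L,
                       svd_dims = 2L,
                       connectivity = 26L,
                       min_size = 27L,
                       seed = 1L) {
  cfg <- list(
    link_threshold_um = as.numeric(link_threshold_um),
    cai_lo_deg = as.numeric(cai_lo_deg),
    cai_hi_deg = as.numeric(cai_hi_deg),
    highlight_cai = as.numeric(highlight_cai),
    bins = as.integer(bins),
    k_clusters = as.integer(k_clusters),
    svd_dims = as.integer(svd_dims),
    connectivity = as.integer(connectivity),
    min_size = as.integer(min_size),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$link_threshold_um > 0,
    cfg$cai_lo_deg >= 0, cfg$cai_lo_deg < cfg$cai_hi_deg, cfg$cai_hi_deg <= 180,
    cfg$bins >= 2L,
    cfg$k_clusters >= 1L,
    cfg$svd_dims >= 1L,
    cfg$connectivity %in% c(6L, 26L),
    cfg$min_size >= 1L
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys fall back to [run_config()]
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}
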