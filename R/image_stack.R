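#' 3D image stack with anisotropic voxel spacing
#'
#' Container for one channel of a 3D confocal/SHG acquisition. The voxel
#' array uses axis order (depth, row, col); `spacing_um` gives the physical
#' edge length of a voxel along each of those axes, in micrometres. The
#' physical coordinate of a voxel centre is its 0-based index times the
#' spacing, so voxel `[1,1,1]` (R indexing) sits at the origin.
#'
#' @param voxels 3D numeric array of non-negative, finite intensities,
#'   axis order (depth, row, col).
#' @param spacing_um numeric 3-vector of voxel edge lengths in micrometres,
#'   in the same (depth, row, col) order. Strictly positive.
#' @param channel_name optional label, e.g. `"nuclei"` or `"collagen"`.
#'
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(0, c(4, 4, 4)), spacing_um = c(2, 1, 1))
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing_um = c(1, 1, 1), channel_name = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array (depth, row, col)", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("all stack dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(voxels))) stop("intensities must be finite", call. = FALSE)
  if (any(voxels < 0)) stop("intensities must be non-negative", call. = FALSE)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || !all(is.finite(spacing_um)) || any(spacing_um <= 0)) {
    stop("`spacing_um` must be 3 strictly positive numbers", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing_um = spacing_um,
         channel_name = as.character(channel_name)[1]),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %s%d x %d x %d voxels (depth x row x col), spacing %.3g x %.3g x %.3g um\n",
    if (nzchar(x$channel_name)) paste0("[", x$channel_name, "] ") else "",
    d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

# Physical coordinates (um) of voxel centres along one axis.
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

# n_total x 3 matrix of voxel-centre coordinates in um, (depth,row,col) order,
# column-major voxel order (first axis fastest) to match which()/arrayInd().
voxel_centers_um <- function(shape, spacing_um) {
  g <- expand.grid(
    d1 = axis_coords(shape[1], spacing_um[1]),
    d2 = axis_coords(shape[2], spacing_um[2]),
    d3 = axis_coords(shape[3], spacing_um[3]),
    KEEP.OUT.ATTRS = FALSE
  )
  unname(as.matrix(g))
}

#' Read one channel of a multi-page TIFF as an image stack
#'
#' Pages are interpreted as z-slices; for multi-channel files the channels
#' of a slice are stored on consecutive pages (channel-fastest interleaving,
#' as written by [write_stack()] and by ImageJ hyperstacks saved in
#' xyczt order). Intensities are read as stored (16-bit unsigned integers
#' for files written by [write_stack()]).
#'
#' @param path path to an existing multi-page TIFF.
#' @param channel 1-based channel index to extract.
#' @param n_channels number of interleaved channels in the file.
#' @param spacing_um voxel spacing in micrometres, (depth, row, col).
#' @param channel_name optional label stored on the result.
#'
#' @return An [image_stack()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, channel = 1L, n_channels = 1L,
                       spacing_um = c(1, 1, 1), channel_name = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  channel <- as.integer(channel)
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("`n_channels` must be >= 1", call. = FALSE)
  if (channel < 1L || channel > n_channels) {
    stop(sprintf("channel %d out of range for a %d-channel file", channel, n_channels),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% n_channels != 0L) {
    stop(sprintf("file has %d pages, not a multiple of n_channels = %d",
                 length(pages), n_channels), call. = FALSE)
  }
  keep <- pages[seq(channel, length(pages), by = n_channels)]
  if (any(!vapply(keep, is.matrix, logical(1)))) {
    stop("TIFF pages must be single-plane greyscale images", call. = FALSE)
  }
  vox <- aperm(simplify2array(keep), c(3, 1, 2)) # (z, row, col)
  image_stack(vox, spacing_um = spacing_um, channel_name = channel_name)
}

#' Write one or more image stacks to a multi-page TIFF
#'
#' Channels are interleaved channel-fastest (all channels of slice 1, then
#' slice 2, ...). Intensities are rounded to the nearest integer and stored
#' as 16-bit unsigned samples, so integer-valued stacks in `[0, 65535]`
#' roundtrip exactly through [read_stack()].
#'
#' @param stacks an [image_stack()] or list of them (all the same shape).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stacks, path) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  shapes <- vapply(stacks, function(s) dim(s$voxels), integer(3))
  if (!all(shapes == shapes[, 1])) stop("all channels must share one shape", call. = FALSE)
  nz <- shapes[1, 1]
  pages <- vector("list", nz * length(stacks))
  for (z in seq_len(nz)) {
    for (ch in seq_along(stacks)) {
      v <- round(matrix(stacks[[ch]]$voxels[z, , ],
                        nrow = shapes[2, 1], ncol = shapes[3, 1]))
      if (any(v < 0 | v > 65535)) {
        stop("intensities must lie in [0, 65535] for 16-bit storage", call. = FALSE)
      }
      pages[[(z - 1L) * length(stacks) + ch]] <- v / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE,
                  compression = "none")
  invisible(path)
}
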