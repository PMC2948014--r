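#' Otsu threshold of an image stack
#'
#' Exhaustively searches the intensity histogram for the threshold that
#' minimizes the intra-class variance
#' `sigma_w^2(t) = p1(t) * sigma_1^2(t) + p2(t) * sigma_2^2(t)`,
#' where class 1 (background) holds intensities `<= t` and class 2
#' (foreground) intensities `> t`, `p1`/`p2` are the class probabilities
#' and `sigma_1^2`/`sigma_2^2` the class variances. Ties are broken toward
#' the lowest threshold so the result is deterministic.
#'
#' @param stack an [image_stack()], or a numeric vector of intensities.
#' @param levels if the data carries more than `levels` distinct values it
#'   is binned into `levels` uniform histogram bins first (default 256, the
#'   conventional greyscale resolution). Data with few distinct values is
#'   thresholded on its exact empirical histogram.
#' @return An `otsu_split`: list with `threshold`, class probabilities
#'   `p1`, `p2`, class variances `var1`, `var2`, and
#'   `intra_class_variance`.
#' @examples
#' s <- image_stack(array(rep(c(10, 200), each = 32), c(4, 4, 4)))
#' otsu_threshold(s)$intra_class_variance # 0
#' @export
otsu_threshold <- function(stack, levels = 256L) {
  x <- if (inherits(stack, "image_stack")) as.vector(stack$voxels) else as.numeric(stack)
  if (!length(x)) stop("no intensities supplied", call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    stop("constant image: Otsu thresholding needs at least two distinct intensities",
         call. = FALSE)
  }
  binned <- length(ux) > levels
  if (binned) {
    # uniform binning; candidate thresholds are bin upper edges, values are
    # represented by bin centres
    br <- seq(min(x), max(x), length.out = levels + 1L)
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
    val <- (br[-1] + br[-(levels + 1L)]) / 2
  } else {
    cnt <- tabulate(match(x, ux), nbins = length(ux))
    val <- ux
  }
  n <- sum(cnt)
  p <- cnt / n
  # cumulative moments up to and including value i (class 1 = values <= t)
  w1 <- cumsum(p)
  m1 <- cumsum(p * val)
  s1 <- cumsum(p * val^2)
  w2 <- 1 - w1
  mu1 <- m1 / w1
  mu2 <- (m1[length(m1)] - m1) / w2
  v1 <- s1 / w1 - mu1^2
  v2 <- (s1[length(s1)] - s1) / w2 - mu2^2
  i <- seq_len(length(val) - 1L) # last cut leaves class 2 empty
  wcv <- w1[i] * pmax(v1[i], 0) + w2[i] * pmax(v2[i], 0)
  wcv[w1[i] == 0 | w2[i] == 0] <- NA # degenerate one-class cuts
  best <- i[which.min(wcv)] # which.min takes the first (lowest) minimiser
  # threshold placed so that class 1 = intensities <= threshold exactly:
  # observed value (exact histogram) or upper bin edge (binned histogram)
  thr <- if (binned) br[best + 1L] else val[best]
  structure(
    list(
      threshold = thr,
      p1 = w1[best], p2 = w2[best],
      var1 = max(v1[best], 0), var2 = max(v2[best], 0),
      intra_class_variance = wcv[best]
    ),
    class = "otsu_split"
  )
}

#' @export
print.otsu_split <- function(x, ...) {
  cat(sprintf(
    "<otsu_split> threshold %.6g  (p1 %.3f, p2 %.3f, intra-class var %.6g)\n",
    x$threshold, x$p1, x$p2, x$intra_class_variance))
  invisible(x)
}

#' Label connected components of a 3D binary mask
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (face neighbours) or 26 (face, edge and corner
#'   neighbours).
#' @return Integer array of the same shape; 0 = background, components
#'   numbered 1..K in order of their first voxel in column-major scan.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  connectivity <- as.integer(connectivity)
  stopifnot(connectivity %in% c(6L, 26L))
  dm <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dm)
  if (!length(idx)) return(out)

  off <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  # keep one of each +/- pair: lexicographically positive offsets
  pos <- off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
    (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0)
  off <- off[pos, , drop = FALSE]

  rank <- array(0L, dm)
  rank[idx] <- seq_along(idx)
  ai <- arrayInd(idx, dm)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ai, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * (dm[1] * dm[2]) + (nb[ok, 2] - 1L) * dm[1] + nb[ok, 1]
    nb_rank <- rank[lin]
    hit <- nb_rank > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb_rank[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber components by first occurrence in scan order
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  out[idx] <- relab[memb]
  out
}

#' Segment nuclei and extract centres of mass
#'
#' Thresholds the nuclei channel (foreground = intensity strictly above
#' the Otsu threshold), labels connected components, discards components
#' smaller than `min_size` voxels, and reports each nucleus centre of mass
#' as the unweighted mean of its member voxel centres, converted to
#' micrometres via the stack spacing. Connectivity is evaluated on the
#' voxel grid; anisotropic spacing enters only at the centroid conversion.
#'
#' @param stack nuclei-channel [image_stack()].
#' @param split an `otsu_split` from [otsu_threshold()], or `NULL` to
#'   compute one; a plain number is taken as a manual threshold.
#' @param connectivity 6 or 26 (default 26: compact blobs, merges diagonal
#'   stair-steps).
#' @param min_size smallest component retained, in voxels (default 27,
#'   i.e. a 3x3x3 block; rejects shot noise).
#' @return Tibble with one row per nucleus: `id`, `x_um`, `y_um`, `z_um`
#'   (centre of mass; x = col axis, y = row axis, z = depth axis),
#'   `voxels`. Empty, with a warning, when nothing is above threshold.
#' @export
segment_nuclei <- function(stack, split = NULL, connectivity = 26L, min_size = 27L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(split)) split <- otsu_threshold(stack)
  thr <- if (inherits(split, "otsu_split")) split$threshold else as.numeric(split)
  mask <- stack$voxels > thr
  empty <- tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                          z_um = numeric(), voxels = integer())
  if (!any(mask)) {
    warning("no voxels above threshold; returning empty nucleus set")
    return(empty)
  }
  lab <- label_components(mask, connectivity)
  idx <- which(lab > 0L)
  ai <- arrayInd(idx, dim(lab))
  sp <- stack$spacing_um
  df <- tibble::tibble(
    comp = lab[idx],
    z = (ai[, 1] - 1) * sp[1],
    y = (ai[, 2] - 1) * sp[2],
    x = (ai[, 3] - 1) * sp[3]
  )
  out <- df |>
    dplyr::summarise(
      z_um = mean(.data$z), y_um = mean(.data$y), x_um = mean(.data$x),
      voxels = dplyr::n(), .by = "comp"
    ) |>
    dplyr::filter(.data$voxels >= min_size) |>
    dplyr::arrange(.data$comp)
  if (!nrow(out)) {
    warning("all components smaller than min_size; returning empty nucleus set")
    return(empty)
  }
  tibble::tibble(
    id = seq_len(nrow(out)),
    x_um = out$x_um, y_um = out$y_um, z_um = out$z_um,
    voxels = as.integer(out$voxels)
  )
}
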