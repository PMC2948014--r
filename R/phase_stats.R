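#' Weighted two-sample Kolmogorov-Smirnov comparison of angle data
#'
#' Compares two sets of angle observations after clipping both to the
#' `[60, 120]` degree window (the KS statistic is most sensitive near the
#' centre of a distribution, and perfect alignment lives at 90 degrees,
#' so discarding the tails does not disturb the comparison). Each sample's
#' empirical CDF is built with step heights proportional to the
#' observation weights; `D` is the maximum absolute difference between
#' the two ECDFs. The p-value uses the asymptotic two-sample Kolmogorov
#' distribution with magnitude-weighted effective sample sizes
#' `n_eff = (sum w)^2 / sum(w^2)`; with unit weights this reduces exactly
#' to the textbook unweighted test.
#'
#' @param a,b numeric vectors of angle values (degrees), or
#'   `angle_distribution` objects (bin centres weighted by bin weights).
#' @param weights_a,weights_b optional non-negative weights.
#' @param clip 2-vector window; values outside are discarded. Default
#'   `c(60, 120)`.
#' @param alpha significance level for the reject flag (default 0.05).
#' @return A `ks_result`: list with `D`, `p_value`, `reject_at_5pct`,
#'   `n_eff_1`, `n_eff_2`.
#' @export
ks_compare <- function(a, b, weights_a = NULL, weights_b = NULL,
                       clip = c(60, 120), alpha = 0.05) {
  ua <- unpack_weighted(a, weights_a)
  ub <- unpack_weighted(b, weights_b)
  keep_a <- ua$x >= clip[1] & ua$x <= clip[2] & ua$w > 0
  keep_b <- ub$x >= clip[1] & ub$x <= clip[2] & ub$w > 0
  xa <- ua$x[keep_a]; wa <- ua$w[keep_a]
  xb <- ub$x[keep_b]; wb <- ub$w[keep_b]
  if (!length(xa) || !length(xb)) {
    stop("no observations inside the clip window", call. = FALSE)
  }
  grid <- sort(unique(c(xa, xb)))
  Fa <- weighted_ecdf(xa, wa, grid)
  Fb <- weighted_ecdf(xb, wb, grid)
  D <- max(abs(Fa - Fb))
  n1 <- sum(wa)^2 / sum(wa^2)
  n2 <- sum(wb)^2 / sum(wb^2)
  n <- n1 * n2 / (n1 + n2)
  p <- ks_asymptotic_pvalue(sqrt(n) * D)
  structure(
    list(D = D, p_value = p, reject_at_5pct = p < alpha,
         n_eff_1 = n1, n_eff_2 = n2),
    class = "ks_result"
  )
}

unpack_weighted <- function(x, w) {
  if (inherits(x, "angle_distribution")) {
    keep <- x$weight > 0
    return(list(x = x$bin_center[keep], w = x$weight[keep]))
  }
  x <- as.numeric(x)
  w <- if (is.null(w)) rep(1, length(x)) else as.numeric(w)
  stopifnot(length(w) == length(x), all(is.finite(x)), all(w >= 0))
  list(x = x, w = w)
}

# right-continuous weighted ECDF evaluated on `grid`
weighted_ecdf <- function(x, w, grid) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- findInterval(grid, x)
  c(0, cw)[i + 1L]
}

# asymptotic Kolmogorov survival function Q(t) = 2 sum (-1)^(k-1) exp(-2 k^2 t^2),
# as used by the classical asymptotic two-sample test
ks_asymptotic_pvalue <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "<ks_result> D = %.4f, p = %.4g (n_eff %.1f vs %.1f)%s\n",
    x$D, x$p_value, x$n_eff_1, x$n_eff_2,
    if (x$reject_at_5pct) "  [distributions differ at 5%]" else ""))
  invisible(x)
}

#' Cluster per-sample angle distributions into remodeling phases
#'
#' Centres the rows of a samples-by-bins pdf matrix, reduces them to
#' `svd_dims` dimensions with an SVD, and clusters the projections with
#' k-means (default k = 3, matching the three phases of early collagen
#' compaction; at least 10 restarts under a fixed seed so the assignment
#' is reproducible). When time points and per-sample CAI values are
#' supplied, clusters are named: the cluster holding the earliest time
#' point is phase I, the cluster holding the maximum-CAI sample is phase
#' III, and the remainder II.
#'
#' @param pdf_matrix numeric matrix, one row per sample, rows summing
#'   to 1 (e.g. pooled angle pdfs). Row names label the samples.
#' @param k number of clusters (default 3).
#' @param svd_dims dimensions kept after SVD (default 2).
#' @param seed integer seed for k-means restarts.
#' @param time optional numeric vector (e.g. days) per sample.
#' @param cai optional numeric CAI per sample.
#' @param nstart k-means restarts (>= 10).
#' @return A `phase_assignment`: list with `assignments` (tibble `sample`,
#'   `cluster`, `phase`, `time`, `cai`), `projection` (samples x svd_dims
#'   matrix), `centers`, `k`, `svd_dims`.
#' @export
cluster_phases <- function(pdf_matrix, k = 3L, svd_dims = 2L, seed = 1L,
                           time = NULL, cai = NULL, nstart = 10L) {
  X <- as.matrix(pdf_matrix)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  stopifnot(svd_dims >= 1L, nstart >= 1L)
  rs <- rowSums(X)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("rows do not sum to 1; normalizing")
    X <- X / rs
  }
  labels <- rownames(X) %||% as.character(seq_len(n))
  Xc <- sweep(X, 2, colMeans(X))
  d <- min(svd_dims, n, ncol(X))
  sv <- svd(Xc, nu = 0, nv = d)
  proj <- Xc %*% sv$v
  km <- withr::with_seed(seed, {
    stats::kmeans(proj, centers = k, nstart = max(10L, nstart), iter.max = 100L)
  })
  cluster <- km$cluster
  phase <- phase_names(cluster, k, time, cai)
  structure(
    list(
      assignments = tibble::tibble(
        sample = labels, cluster = as.integer(cluster), phase = phase,
        time = if (is.null(time)) NA_real_ else as.numeric(time),
        cai = if (is.null(cai)) NA_real_ else as.numeric(cai)
      ),
      projection = proj, centers = km$centers, k = k, svd_dims = d
    ),
    class = "phase_assignment"
  )
}

# cluster ids -> roman phase names; anchored when time/cai metadata exist
phase_names <- function(cluster, k, time, cai) {
  roman <- as.character(utils::as.roman(seq_len(k)))
  if (k == 3L && !is.null(time) && !is.null(cai)) {
    c1 <- cluster[which.min(time)] # earliest time point -> I
    c3 <- cluster[which.max(cai)]  # peak alignment -> III
    if (c1 != c3) {
      map <- rep("II", k)
      map[c1] <- "I"; map[c3] <- "III"
      return(map[cluster])
    }
  }
  # fallback: number clusters by first appearance
  map <- integer(k)
  map[unique(cluster)] <- seq_along(unique(cluster))
  roman[map[cluster]]
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat(sprintf("<phase_assignment> %d samples in %d clusters (svd_dims = %d)\n",
              nrow(x$assignments), x$k, x$svd_dims))
  print(x$assignments)
  invisible(x)
}
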