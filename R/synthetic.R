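#' Synthetic smoothed symmetric statistic matrix
#'
#' Emulates an edgewise t-statistic matrix: an `N x N` standard-normal draw
#' is smoothed with a zero-padded 2D Gaussian filter (introducing the spatial
#' correlation structure expected of FC statistics), symmetrized by averaging
#' with its transpose, and (by default) rescaled so the off-diagonal entries
#' have unit standard deviation, restoring the t-like marginal scale that the
#' filter shrinks.  The filter width scales proportionally with `N`
#' (default `sigma = n_rois / 40`), keeping the correlation length a constant
#' fraction of the parcellation across sizes.
#'
#' @param n_rois Number of ROIs (`>= 2`).
#' @param filter_sigma Gaussian filter SD in matrix-index units (`>= 0`; 0
#'   skips smoothing).
#' @param seed Integer seed; the generator is bit-reproducible.
#' @param rescale Rescale off-diagonals to unit SD after smoothing.
#' @return A [stat_matrix()].
#' @examples
#' m <- synth_stat_matrix(20, seed = 1)
#' max(abs(m - t(m)))  # 0
#' @export
synth_stat_matrix <- function(n_rois, filter_sigma = n_rois / 40, seed = 1,
                              rescale = TRUE) {
  stopifnot(n_rois >= 2, filter_sigma >= 0)
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_rois * n_rois), n_rois, n_rois)
  })
  a <- gaussian_filter_2d(a, filter_sigma)
  a <- (a + t(a)) / 2
  if (rescale) {
    s <- sd(a[upper.tri(a)])
    if (s > 0) a <- a / s
  }
  stat_matrix(a)
}

#' Zero-padded separable 2D Gaussian filter
#'
#' Convolves a matrix with an isotropic Gaussian kernel truncated at
#' `4 * sigma`, treating everything outside the matrix as zero (constant-zero
#' boundary, no kernel renormalization at the edges).
#'
#' @param x Numeric matrix.
#' @param sigma Kernel SD; `sigma <= 0` returns `x` unchanged.
#' @return The filtered matrix.
#' @export
gaussian_filter_2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n1 <- nrow(x); n2 <- ncol(x)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- matrix(0, n, n)
    inb <- d <= r
    K[inb] <- k[d[inb] + r + 1L]
    K
  }
  band(n1) %*% x %*% t(band(n2))
}

#' Synthetic two-group FC dataset with a planted effect
#'
#' Per-subject symmetric matrices are iid Gaussian noise (`sd = noise_sd`);
#' subjects in group 2 (two-sample design) or all subjects (one-sample
#' design) get `effect_size * noise_sd` added at the effect edges.  Effect
#' edges come either from a node block (`effect_nodes`: every edge within the
#' block) or an explicit edge tibble (`effect_edges` with columns `u`, `v`).
#'
#' @param n_sub Subjects per group (two-sample) or in total (one-sample);
#'   at least 2 per group and 4 in total.
#' @param n_rois Number of ROIs.
#' @param effect_nodes Integer vector of ROI indices forming the effect
#'   block, or `NULL`.
#' @param effect_edges Tibble of explicit effect edges, or `NULL`.
#' @param effect_size Mean shift at effect edges, in units of `noise_sd`.
#' @param noise_sd Subject-level noise SD (> 0).
#' @param design `"two_sample"` or `"one_sample"`.
#' @param seed Integer seed.
#' @return A [group_dataset()].
#' @export
synth_group_dataset <- function(n_sub, n_rois, effect_nodes = NULL,
                                effect_edges = NULL, effect_size = 0,
                                noise_sd = 1, design = c("two_sample", "one_sample"),
                                seed = 1) {
  design <- match.arg(design)
  stopifnot(n_rois >= 2, noise_sd > 0)
  total <- if (design == "two_sample") 2L * n_sub else n_sub
  if (total < 4L || (design == "two_sample" && n_sub < 2L))
    abort("need at least 4 subjects in total and 2 per group",
          class = "ictfce_bad_params")
  pairs <- matrix_to_edges(stat_matrix(matrix(0, n_rois, n_rois), tol = Inf))
  eff <- logical(nrow(pairs))
  if (!is.null(effect_nodes)) {
    stopifnot(all(effect_nodes >= 1), all(effect_nodes <= n_rois))
    eff <- eff | (pairs$u %in% effect_nodes & pairs$v %in% effect_nodes)
  }
  if (!is.null(effect_edges)) {
    if (any(effect_edges$u == effect_edges$v))
      abort("effect edges must not touch the diagonal", class = "ictfce_bad_params")
    stopifnot(all(effect_edges$u >= 1), all(effect_edges$v <= n_rois))
    key <- paste(pmin(effect_edges$u, effect_edges$v),
                 pmax(effect_edges$u, effect_edges$v))
    eff <- eff | (paste(pairs$u, pairs$v) %in% key)
  }
  ne <- nrow(pairs)
  withr::with_seed(seed, {
    x <- matrix(rnorm(total * ne, sd = noise_sd), total, ne)
  })
  group <- if (design == "two_sample")
    rep(c(1L, 2L), each = n_sub) else rep(1L, total)
  shifted <- if (design == "two_sample") group == 2L else rep(TRUE, total)
  if (any(eff) && effect_size != 0)
    x[shifted, eff] <- x[shifted, eff] + effect_size * noise_sd
  group_dataset(x, group, n_rois = n_rois, edges = pairs[c("u", "v")],
                effect_edges = which(eff))
}

#' Synthetic voxel statistic volume
#'
#' Gaussian blobs of the given peak amplitude on a zero background, plus
#' optional iid Gaussian noise; the mask is all-inclusive unless supplied.
#'
#' @param shape Integer length-3 volume shape.
#' @param n_blobs Number of blobs (0 for pure background).
#' @param blob_sigma Blob SD in voxels.
#' @param peak Blob peak amplitude.
#' @param noise_sd Additive noise SD (0 for none).
#' @param mask Optional logical array.
#' @param connectivity Adjacency rule, see [voxel_image()].
#' @param seed Integer seed.
#' @return A [voxel_image()].
#' @export
synth_voxel_image <- function(shape, n_blobs = 1, blob_sigma = 2, peak = 5,
                              noise_sd = 0, mask = NULL, connectivity = 26,
                              seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  stats <- array(0, shape)
  withr::with_seed(seed, {
    if (n_blobs > 0) {
      centers <- cbind(runif(n_blobs, 1, shape[1]),
                       runif(n_blobs, 1, shape[2]),
                       runif(n_blobs, 1, shape[3]))
      co <- arrayInd(seq_len(prod(shape)), shape)
      for (b in seq_len(n_blobs)) {
        d2 <- (co[, 1] - centers[b, 1])^2 + (co[, 2] - centers[b, 2])^2 +
              (co[, 3] - centers[b, 3])^2
        stats <- stats + array(peak * exp(-d2 / (2 * blob_sigma^2)), shape)
      }
    }
    if (noise_sd > 0)
      stats <- stats + array(rnorm(prod(shape), sd = noise_sd), shape)
  })
  voxel_image(stats, mask = mask, connectivity = connectivity)
}
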