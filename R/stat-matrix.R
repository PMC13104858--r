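#' Construct a validated ROI-by-ROI statistic matrix
#'
#' A `stat_matrix` is the functional-connectivity input object: a symmetric
#' `N x N` matrix of test statistics (e.g. edgewise t values from a group
#' comparison), one row/column per region of interest (ROI).  The diagonal is
#' ignored by every operation in the package.
#'
#' Validation enforces: a square numeric matrix, all entries finite, symmetry
#' within `tol`, and `N >= 2`.  The first offending entry is named in the
#' error message.
#'
#' @param x A square numeric matrix.
#' @param tol Symmetry tolerance; entries with `|x[i,j] - x[j,i]| > tol` fail.
#' @return `x` with class `stat_matrix` and a zeroed diagonal.
#' @examples
#' m <- stat_matrix(matrix(c(0, 3, 1, 3, 0, 2, 1, 2, 0), 3, 3))
#' n_rois(m)
#' @export
stat_matrix <- function(x, tol = 1e-12) {
  if (!is.matrix(x) || !is.numeric(x))
    abort("`x` must be a numeric matrix", class = "ictfce_invalid_matrix")
  n <- nrow(x)
  if (ncol(x) != n)
    abort(sprintf("`x` must be square, got %d x %d", n, ncol(x)),
          class = "ictfce_invalid_matrix")
  if (n < 2)
    abort("a statistic matrix needs at least 2 ROIs", class = "ictfce_invalid_matrix")
  bad <- which(!is.finite(x))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(x))
    abort(sprintf("non-finite statistic at [%d, %d]", ij[1], ij[2]),
          class = "ictfce_invalid_matrix")
  }
  d <- abs(x - t(x))
  if (any(d > tol)) {
    ij <- arrayInd(which.max(d), dim(x))
    abort(sprintf("matrix not symmetric: |x[%d,%d] - x[%d,%d]| = %g exceeds tol %g",
                  ij[1], ij[2], ij[2], ij[1], max(d), tol),
          class = "ictfce_invalid_matrix")
  }
  diag(x) <- 0
  structure(x, class = c("stat_matrix", "matrix", "array"))
}

#' @rdname stat_matrix
#' @export
n_rois <- function(x) nrow(x)

#' @export
print.stat_matrix <- function(x, ...) {
  cat(sprintf("<stat_matrix> %d ROIs, %d edges, max statistic %.4g\n",
              nrow(x), nrow(x) * (nrow(x) - 1) / 2, max(x[upper.tri(x)])))
  invisible(x)
}

#' Extract the edge list of a statistic matrix
#'
#' The complete FC graph on `N` ROIs has exactly `N(N-1)/2` undirected edges;
#' each row is one unordered ROI pair `u < v` with its test statistic read
#' from the upper triangle.  Rows are ordered lexicographically by `(u, v)`.
#'
#' @param m A [stat_matrix()] (or a matrix coercible to one).
#' @return A tibble with integer columns `u`, `v` (1-based ROI indices) and
#'   numeric `stat`.
#' @examples
#' matrix_to_edges(stat_matrix(matrix(c(0, 1, 1, 0), 2, 2)))
#' @export
matrix_to_edges <- function(m) {
  m <- as_stat_matrix(m)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  tibble(u = as.integer(ut[, 1L]), v = as.integer(ut[, 2L]),
         stat = m[ut])
}

as_stat_matrix <- function(m) {
  if (inherits(m, "stat_matrix")) m else stat_matrix(m)
}

#' Rebuild a symmetric matrix from per-edge values
#'
#' @param edges Tibble with `u`, `v` and a value column.
#' @param n_rois Number of ROIs.
#' @param value Name of the value column.
#' @return A symmetric `n_rois x n_rois` matrix with zero diagonal.
#' @export
edges_to_matrix <- function(edges, n_rois, value = "stat") {
  out <- matrix(0, n_rois, n_rois)
  out[cbind(edges$u, edges$v)] <- edges[[value]]
  out[cbind(edges$v, edges$u)] <- edges[[value]]
  out
}

#' Discretization grid for the TFCE integral
#'
#' The discretized TFCE sum uses thresholds `h_k = k * dh` for
#' `k = 1, ..., nth` with `nth = ceiling(tmax / dh)`, so the map's maximum
#' statistic is always covered by the topmost threshold.  (The `h = 0` term
#' contributes nothing for `H > 0`.)
#'
#' @param tmax Maximum positive statistic in the map.
#' @param dh Integration step size (> 0).
#' @return A list of class `threshold_grid` with `tmax`, `dh`, `nth` and the
#'   vector `thresholds`.
#' @examples
#' build_threshold_grid(10, 0.25)$nth  # 40
#' @export
build_threshold_grid <- function(tmax, dh) {
  if (!is.numeric(dh) || length(dh) != 1L || dh <= 0)
    abort("`dh` must be a single positive number", class = "ictfce_bad_params")
  if (!is.numeric(tmax) || length(tmax) != 1L || tmax <= 0)
    abort("no positive statistics: the threshold grid is empty and the TFCE map is all zero",
          class = "ictfce_empty_grid")
  nth <- as.integer(ceiling(tmax / dh))
  structure(list(tmax = tmax, dh = dh, nth = nth,
                 thresholds = seq_len(nth) * dh),
            class = "threshold_grid")
}

#' Threshold bin of a statistic
#'
#' Counts the thresholds `k * dh` satisfied under the non-strict rule
#' `stat >= k * dh`, i.e. `floor(stat / dh)`: a statistic exactly on a
#' threshold belongs to the cluster at that threshold.  Statistics below `dh`
#' (including all non-positive values) get bin 0 and contribute no TFCE mass.
#' Exact floor semantics, no floating tolerance.
#'
#' @param stat Numeric vector of test statistics.
#' @param dh Step size (> 0).
#' @return Integer vector of bin indices (>= 0).
#' @examples
#' bin_index(c(1.0, 0.49, 3.0), dh = 0.5)
#' @export
bin_index <- function(stat, dh) {
  if (!is.numeric(dh) || length(dh) != 1L || dh <= 0)
    abort("`dh` must be a single positive number", class = "ictfce_bad_params")
  pmax(0L, as.integer(floor(stat / dh)))
}

#' TFCE parameters
#'
#' Bundles the extent exponent `E` (> 0), the height exponent `H` (>= 0,
#' `H != -1` is required by the exact engine's closed-form integral) and the
#' step size `dh` (> 0; unused by the exact engine).  Conventional defaults
#' are `E = 0.4, H = 3` for FC data and `E = 0.5, H = 2` for voxel data.
#'
#' @param E Extent exponent.
#' @param H Height exponent.
#' @param dh Integration step, or `NULL` for the exact engine.
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.4, H = 3, dh = 0.1) {
  if (!is.numeric(E) || length(E) != 1L || E <= 0)
    abort("`E` must be a single positive number", class = "ictfce_bad_params")
  if (!is.numeric(H) || length(H) != 1L || H < 0)
    abort("`H` must be a single non-negative number", class = "ictfce_bad_params")
  if (!is.null(dh) && (!is.numeric(dh) || length(dh) != 1L || dh <= 0))
    abort("`dh` must be NULL or a single positive number", class = "ictfce_bad_params")
  structure(list(E = E, H = H, dh = dh), class = "tfce_params")
}
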