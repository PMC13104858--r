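#' Threshold-free cluster enhancement of an FC statistic matrix
#'
#' Transforms every edge statistic into its TFCE value
#' \deqn{TFCE(x) = \int_0^{h_{max}} c(x, h)^E \, h^H \, dh}
#' where `c(x, h)` is the number of edges in the cluster containing edge `x`
#' among edges with statistic at or above `h`, under node-sharing adjacency
#' (two edges are neighbours iff they share an ROI, so clusters are connected
#' subgraphs of the ROI graph).
#'
#' Three engines compute the same quantity:
#' * `"incremental"` (default) - the incremental-cluster algorithm: clusters
#'   are built once from the highest threshold bin downward (each edge either
#'   joins its endpoints' common cluster in O(1) or merges two clusters,
#'   relabeling the smaller; at most `N - 1` merges in total), cluster edge
#'   counts are recorded per node per threshold, and every edge reads its
#'   value from the cumulative accumulator at its bin and either endpoint.
#' * `"reference"` - brute-force discretization that recomputes connected
#'   components from scratch at every threshold; the slow, obviously-correct
#'   oracle.  Numerically equal to `"incremental"` up to summation order.
#' * `"exact"` - no discretization: the integral is evaluated in closed form
#'   piecewise between consecutive sorted statistic values (`dh` must not be
#'   supplied).
#'
#' Only the positive tail is enhanced: edges with `stat < dh` (or `<= 0` for
#' the exact engine) get TFCE 0.  For the negative tail, run the negated
#' matrix.
#'
#' @param m A [stat_matrix()] (or plain symmetric matrix).
#' @param E Extent exponent (> 0); FC convention 0.4.
#' @param H Height exponent (>= 0); FC convention 3.
#' @param dh Integration step (> 0).  Forbidden with `method = "exact"`.
#' @param method One of `"incremental"`, `"reference"`, `"exact"`.
#' @param max_cells Accumulator budget: the incremental engine refuses to
#'   allocate more than this many `nth * N` cells.
#' @return A symmetric `N x N` matrix of class `tfce_map` with zero diagonal;
#'   attributes `method`, `params`, `tmax`, `nth` and (incremental engine)
#'   `merges`.
#' @examples
#' m <- stat_matrix(matrix(c(0, 3, 1, 3, 0, 2, 1, 2, 0), 3, 3))
#' tfce_fc(m, E = 1, H = 1, dh = 1)
#' tfce_fc(m, E = 1, H = 1, method = "exact")
#' @export
tfce_fc <- function(m, E = 0.4, H = 3, dh = 0.1,
                    method = c("incremental", "reference", "exact"),
                    max_cells = 1e8) {
  method <- match.arg(method)
  m <- as_stat_matrix(m)
  if (method == "exact" && !missing(dh))
    abort("`dh` does not apply to the exact engine (remove it or pick a discretized method)",
          class = "ictfce_bad_params")
  p <- tfce_params(E, H, if (method == "exact") NULL else dh)
  ed <- matrix_to_edges(m)
  n <- n_rois(m)
  extra <- list()
  if (method == "exact") {
    val <- cpp_tfce_exact_fc(n, ed$u - 1L, ed$v - 1L, ed$stat, E, H)
  } else if (method == "reference") {
    val <- cpp_tfce_reference(n, ed$u - 1L, ed$v - 1L, ed$stat, E, H, dh)
  } else {
    res <- cpp_tfce_ic(n, ed$u - 1L, ed$v - 1L, ed$stat, E, H, dh,
                       keep_state = FALSE, max_cells = max_cells)
    val <- res$tfce
    extra <- list(merges = res$merges)
  }
  ed$tfce <- val
  out <- edges_to_matrix(ed, n, "tfce")
  tmax <- max(ed$stat)
  structure(out, class = c("tfce_map", "matrix", "array"),
            method = method, params = p,
            tmax = tmax,
            nth = if (method != "exact" && tmax > 0)
              build_threshold_grid(tmax, dh)$nth else NA_integer_,
            merges = extra$merges)
}

#' @rdname tfce_fc
#' @export
tfce_exact <- function(m, E = 0.4, H = 3) tfce_fc(m, E, H, method = "exact")

#' @export
print.tfce_map <- function(x, ...) {
  cat(sprintf("<tfce_map> %d ROIs, engine '%s', max TFCE %.6g\n",
              nrow(x), attr(x, "method"), max(x)))
  invisible(x)
}

#' @export
as_tibble.tfce_map <- function(x, ...) {
  ed <- matrix_to_edges(unclass_map(x))
  names(ed)[names(ed) == "stat"] <- "tfce"
  ed
}

unclass_map <- function(x) {
  class(x) <- c("matrix", "array")
  stat_matrix(x, tol = Inf)
}

#' Inspect the incremental engine's accumulation state
#'
#' Runs the incremental pass and returns its internal node-accumulation
#' structure: `S[k, v]` is the edge count of the cluster containing node `v`
#' at threshold `k * dh` (0 for inactive nodes), and
#' `F[k, v] = sum_{j <= k} S[j, v]^E (j dh)^H dh` is the cumulative TFCE
#' integral.  `S` is non-increasing down the rows only in the sense that
#' clusters grow as the threshold falls (i.e. non-increasing in `k` for fixed
#' `v`), and for every edge with bin `>= 1`, `F[bin, u] == F[bin, v]` exactly.
#'
#' @inheritParams tfce_fc
#' @return A list with `S` (`nth x N` integer matrix), `F` (`nth x N`
#'   numeric), `tfce` ([tfce_fc()]-style map), `merges` (total cluster merges,
#'   always `<= N - 1`), `grid` (the [build_threshold_grid()] used) and the
#'   input edge tibble `edges` with a `bin` column.
#' @export
ic_tfce_state <- function(m, E = 0.4, H = 3, dh = 0.1, max_cells = 1e8) {
  m <- as_stat_matrix(m)
  ed <- matrix_to_edges(m)
  n <- n_rois(m)
  tmax <- max(ed$stat)
  if (tmax <= 0) {
    return(list(S = matrix(0L, 0, n), F = matrix(0, 0, n),
                tfce = edges_to_matrix(dplyr::mutate(ed, tfce = 0), n, "tfce"),
                merges = 0L, grid = NULL,
                edges = dplyr::mutate(ed, bin = 0L, tfce = 0)))
  }
  res <- cpp_tfce_ic(n, ed$u - 1L, ed$v - 1L, ed$stat, E, H, dh,
                     keep_state = TRUE, max_cells = max_cells)
  ed$bin <- bin_index(ed$stat, dh)
  ed$tfce <- res$tfce
  list(S = res$S, F = res$F,
       tfce = edges_to_matrix(ed, n, "tfce"),
       merges = res$merges,
       grid = build_threshold_grid(tmax, dh),
       edges = ed)
}

#' O(1) edge retrieval from the accumulator
#'
#' Reads an edge's TFCE value by indexing the cumulative accumulator `F` at
#' the edge's threshold bin and either endpoint node; both endpoints give the
#' same value because they share a cluster at every threshold the edge
#' survives.
#'
#' @param state A list from [ic_tfce_state()].
#' @param u,v Endpoint ROI indices (1-based, `u != v`).
#' @return The edge's TFCE value (0 when its statistic falls below `dh`).
#' @export
lookup_edge <- function(state, u, v) {
  s <- state$edges$stat[state$edges$u == min(u, v) & state$edges$v == max(u, v)]
  if (length(s) != 1L) abort("no such edge", class = "ictfce_bad_params")
  if (is.null(state$grid)) return(0)
  b <- bin_index(s, state$grid$dh)
  if (b == 0L) return(0)
  state$F[b, u]
}

#' Connected clusters of supra-threshold edges
#'
#' Restricts the FC graph to edges with `stat >= h` and labels connected
#' components under node-sharing adjacency, reporting each cluster's edge and
#' node counts.  Component labeling is delegated to \pkg{igraph}; this is the
#' independent per-threshold clustering used to cross-check the TFCE engines.
#'
#' @param edges Edge tibble from [matrix_to_edges()].
#' @param h Threshold (> 0).
#' @param n_nodes Number of ROIs (defaults to the largest endpoint index).
#' @return A list with `nodes` (tibble `node`, `cluster`) covering active
#'   nodes only, `clusters` (tibble `cluster`, `n_nodes`, `n_edges`) and
#'   `edges` (the supra-threshold edges with their `cluster`).
#' @export
clusters_at_threshold <- function(edges, h, n_nodes = max(edges$v)) {
  stopifnot(h > 0)
  keep <- edges$stat >= h
  sub <- edges[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(nodes = tibble(node = integer(), cluster = integer()),
                clusters = tibble(cluster = integer(), n_nodes = integer(),
                                  n_edges = integer()),
                edges = dplyr::mutate(sub, cluster = integer(0))))
  }
  g <- igraph::graph_from_edgelist(cbind(sub$u, sub$v), directed = FALSE)
  comp <- igraph::components(g)
  active <- sort(unique(c(sub$u, sub$v)))
  nodes <- tibble(node = active, cluster = comp$membership[active])
  sub$cluster <- comp$membership[sub$u]
  clusters <- dplyr::summarise(dplyr::group_by(nodes, .data$cluster),
                               n_nodes = dplyr::n(), .groups = "drop")
  ecnt <- dplyr::summarise(dplyr::group_by(sub, .data$cluster),
                           n_edges = dplyr::n(), .groups = "drop")
  clusters <- dplyr::left_join(clusters, ecnt, by = "cluster")
  list(nodes = nodes, clusters = clusters, edges = sub)
}

#' Closed-form integral of h^H over an interval
#'
#' `interval_integral(a, b, H)` is `(b^(H+1) - a^(H+1)) / (H + 1)`, the
#' building block of the exact TFCE: between two consecutive sorted statistic
#' values every cluster size is constant, so the extent factor leaves the
#' integral.
#'
#' @param a,b Interval bounds, `0 <= a <= b`.
#' @param H Height exponent, `H != -1`.
#' @return The integral value.
#' @examples
#' interval_integral(1, 2, H = 1)  # 1.5
#' @export
interval_integral <- function(a, b, H) {
  if (any(H == -1)) abort("H = -1 is unsupported (log case)", class = "ictfce_bad_params")
  stopifnot(all(a >= 0), all(b >= a))
  (b^(H + 1) - a^(H + 1)) / (H + 1)
}

#' Running-cluster bookkeeping: flush a cluster down to a height
#'
#' A running cluster tracks its size, the last height at which its score was
#' updated, and an accumulated score.  Flushing adds the closed-form
#' contribution `size^E * interval_integral(down_to, last_flushed_height, H)`
#' and moves `last_flushed_height` down to `down_to`; a zero-length interval
#' changes nothing.
#'
#' @param cluster A list with fields `edge_count`, `last_flushed_height`,
#'   `accumulated_score`.
#' @param down_to New (lower or equal) height.
#' @param E,H TFCE exponents.
#' @return The updated cluster list.
#' @examples
#' cl <- list(edge_count = 2, last_flushed_height = 2, accumulated_score = 0)
#' flush_cluster(cl, 1, E = 1, H = 1)$accumulated_score  # 3
#' @export
flush_cluster <- function(cluster, down_to, E, H) {
  if (down_to > cluster$last_flushed_height)
    abort("cannot flush upward: `down_to` exceeds the last flushed height",
          class = "ictfce_flush_order")
  if (down_to < cluster$last_flushed_height) {
    cluster$accumulated_score <- cluster$accumulated_score +
      cluster$edge_count^E *
      interval_integral(down_to, cluster$last_flushed_height, H)
    cluster$last_flushed_height <- down_to
  }
  cluster
}
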