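#' Voxel statistic volume
#'
#' Bundles a 3D array of test statistics with a binary inclusion mask and a
#' spatial adjacency rule: 6-connectivity (face-sharing), 18 (face + edge) or
#' 26 (face + edge + corner).  Out-of-mask voxels are absent from every
#' downstream computation, not zero-statistic nodes.
#'
#' @param stats 3D numeric array.
#' @param mask 3D logical array of the same shape, or `NULL` for all-in.
#' @param connectivity 6, 18 or 26.
#' @return A list of class `voxel_image`.
#' @export
voxel_image <- function(stats, mask = NULL, connectivity = 26) {
  if (length(dim(stats)) != 3L)
    abort("`stats` must be a 3D array", class = "ictfce_invalid_volume")
  if (is.null(mask)) mask <- array(TRUE, dim(stats))
  if (!identical(dim(mask), dim(stats)))
    abort("mask shape must match the statistic volume", class = "ictfce_invalid_volume")
  mask <- array(as.logical(mask), dim(mask))
  if (!all(is.finite(stats[mask])))
    abort("non-finite statistic inside the mask", class = "ictfce_invalid_volume")
  if (!connectivity %in% c(6, 18, 26))
    abort("connectivity must be 6, 18 or 26", class = "ictfce_invalid_volume")
  structure(list(stats = stats, mask = mask, connectivity = connectivity),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %s, %d in-mask voxels, %d-connectivity\n",
              paste(dim(x$stats), collapse = "x"), sum(x$mask), x$connectivity))
  invisible(x)
}

# neighbour offsets for a connectivity level (all 2*k directions)
conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(g != 0)
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  unname(g[keep, , drop = FALSE])
}

#' Convert a voxel volume to an activation-weighted graph
#'
#' The graph transformation that lets voxel data run through the same
#' edge-based clustering machinery as FC data: one node per in-mask voxel,
#' activated at its own statistic value, and one edge per spatially adjacent
#' in-mask pair, weighted by the minimum of the two endpoint statistics.  At
#' any threshold `h`, the subgraph of nodes with statistic `>= h` and edges
#' with weight `>= h` has exactly the same connected components as the
#' thresholded binary volume, so graph clustering and 3D component labeling
#' agree voxel-for-voxel.
#'
#' @param img A [voxel_image()].
#' @return A list of class `voxel_graph` with `nodes` (tibble `node`, `x`,
#'   `y`, `z`, `stat`), `edges` (tibble `u`, `v`, `weight` with `u < v`),
#'   `dims`, `index` (linear array indices of the nodes) and `connectivity`.
#' @export
voxel_to_graph <- function(img) {
  stopifnot(inherits(img, "voxel_image"))
  dims <- dim(img$stats)
  idx <- which(img$mask)
  if (length(idx) == 0L)
    return(structure(list(nodes = tibble(node = integer(), x = integer(),
                                         y = integer(), z = integer(),
                                         stat = numeric()),
                          edges = tibble(u = integer(), v = integer(),
                                         weight = numeric()),
                          dims = dims, index = idx,
                          connectivity = img$connectivity),
                     class = "voxel_graph"))
  node_id <- array(NA_integer_, dims)
  node_id[idx] <- seq_along(idx)
  co <- arrayInd(idx, dims)
  nodes <- tibble(node = seq_along(idx),
                  x = co[, 1L], y = co[, 2L], z = co[, 3L],
                  stat = img$stats[idx])
  offs <- conn_offsets(img$connectivity)
  pieces <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[k, ], nrow(co), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
           (nb[ok, 3] - 1L) * dims[1] * dims[2]
    vv <- node_id[lin]
    uu <- nodes$node[ok]
    here <- !is.na(vv) & uu < vv   # each unordered pair kept once
    if (any(here))
      pieces[[k]] <- tibble(u = uu[here], v = vv[here])
  }
  edges <- dplyr::bind_rows(pieces)
  if (nrow(edges)) {
    edges <- dplyr::arrange(edges, .data$u, .data$v)
    edges$weight <- pmin(nodes$stat[edges$u], nodes$stat[edges$v])
  } else {
    edges <- tibble(u = integer(), v = integer(), weight = numeric())
  }
  structure(list(nodes = nodes, edges = edges, dims = dims, index = idx,
                 connectivity = img$connectivity),
            class = "voxel_graph")
}

#' @export
print.voxel_graph <- function(x, ...) {
  cat(sprintf("<voxel_graph> %d nodes, %d edges (%d-connectivity)\n",
              nrow(x$nodes), nrow(x$edges), x$connectivity))
  invisible(x)
}

#' TFCE of a voxel statistic volume
#'
#' Runs TFCE on the graph representation of a voxel volume.  Cluster size
#' counts voxels (not edges, unlike the FC engine): isolated supra-threshold
#' voxels are singleton clusters of size 1.  Engines as in [tfce_fc()]:
#' the incremental engine activates nodes at their own statistic bin before
#' the same-bin edges and accumulates each voxel's TFCE directly after every
#' bin; the reference engine labels the thresholded volume per step via
#' [voxel_clusters_reference()]; the exact engine integrates piecewise
#' between consecutive sorted activation heights.
#'
#' @param img A [voxel_image()].
#' @param E Extent exponent; voxel convention 0.5.
#' @param H Height exponent; voxel convention 2.
#' @param dh Integration step (forbidden for `method = "exact"`).
#' @param method `"incremental"`, `"reference"` or `"exact"`.
#' @return A 3D array of TFCE values (0 outside the mask) with attributes
#'   `method`, `params`, `tmax`, `nth`, `merges`.
#' @examples
#' img <- voxel_image(array(c(2, 5, 3, 0.5), c(4, 1, 1)))
#' tfce_voxel(img, E = 1, H = 1, dh = 1)[2, 1, 1]  # 24
#' @export
tfce_voxel <- function(img, E = 0.5, H = 2, dh = 0.1,
                       method = c("incremental", "reference", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(img, "voxel_image"))
  if (method == "exact" && !missing(dh))
    abort("`dh` does not apply to the exact engine", class = "ictfce_bad_params")
  g <- voxel_to_graph(img)
  merges <- NA_integer_
  nth <- NA_integer_
  tmax <- if (nrow(g$nodes)) max(g$nodes$stat) else 0
  if (nrow(g$nodes) == 0L) {
    val <- numeric(0)
  } else if (method == "exact") {
    val <- cpp_tfce_exact_voxel(g$nodes$stat, g$edges$u - 1L, g$edges$v - 1L,
                                g$edges$weight, E, H)
  } else if (method == "incremental") {
    res <- cpp_tfce_ic_voxel(g$nodes$stat, g$edges$u - 1L, g$edges$v - 1L,
                             g$edges$weight, E, H, dh)
    val <- res$tfce
    merges <- res$merges
    nth <- res$nth
  } else {
    val <- reference_voxel_tfce(img, E, H, dh)
    if (tmax > 0) nth <- build_threshold_grid(tmax, dh)$nth
  }
  out <- array(0, g$dims)
  out[g$index] <- val
  structure(out, method = method,
            params = tfce_params(E, H, if (method == "exact") NULL else dh),
            tmax = tmax, nth = nth, merges = merges)
}

# brute-force voxel TFCE: threshold -> label -> sum, per step.  Uses the
# shared bin rule so boundary statistics agree with the incremental engine.
reference_voxel_tfce <- function(img, E, H, dh) {
  idx <- which(img$mask)
  stat <- img$stats[idx]
  out <- numeric(length(idx))
  tmax <- max(stat)
  if (tmax <= 0) return(out)
  grid <- build_threshold_grid(tmax, dh)
  bins <- bin_index(stat, dh)
  for (k in seq_len(grid$nth)) {
    h <- grid$thresholds[k]
    act <- bins >= k
    if (!any(act)) next
    active <- array(FALSE, dim(img$stats))
    active[idx[act]] <- TRUE
    labels <- label_binary_volume(active, img$connectivity)
    csize <- tabulate(labels[idx[act]])
    out[act] <- out[act] + csize[labels[idx[act]]]^E * h^H * dh
  }
  out
}

#' Reference connected-component labeling of a thresholded volume
#'
#' Labels the binary volume `stats >= h` (inside the mask) by classic 3D
#' connected-component labeling under the image's connectivity.  This is the
#' voxel-space oracle the graph construction of [voxel_to_graph()] must
#' reproduce cluster-for-cluster; components here are computed from
#' adjacency pairs of the thresholded volume via \pkg{igraph}, never through
#' the min-weight edge graph.
#'
#' @param img A [voxel_image()].
#' @param h Threshold (> 0); statistics exactly at `h` are included.
#' @return A list with `labels` (integer array, 0 = inactive) and `clusters`
#'   (tibble `cluster`, `n_voxels`).
#' @export
voxel_clusters_reference <- function(img, h) {
  stopifnot(inherits(img, "voxel_image"), h > 0)
  active <- img$mask & img$stats >= h
  labels <- label_binary_volume(active, img$connectivity)
  act <- labels[labels > 0L]
  sizes <- if (length(act)) tabulate(act) else integer(0)
  list(labels = labels,
       clusters = tibble(cluster = seq_along(sizes),
                         n_voxels = as.integer(sizes)))
}

# 3D connected-component labeling of a logical array via igraph
label_binary_volume <- function(active, connectivity) {
  dims <- dim(active)
  labels <- array(0L, dims)
  idx <- which(active)
  if (length(idx) == 0L) return(labels)
  aid <- array(NA_integer_, dims)
  aid[idx] <- seq_along(idx)
  co <- arrayInd(idx, dims)
  offs <- conn_offsets(connectivity)
  eu <- ev <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[k, ], nrow(co), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
           (nb[ok, 3] - 1L) * dims[1] * dims[2]
    vv <- aid[lin]
    uu <- seq_along(idx)[ok]
    here <- !is.na(vv) & uu < vv
    eu[[k]] <- uu[here]
    ev[[k]] <- vv[here]
  }
  el <- cbind(as.integer(unlist(eu)), as.integer(unlist(ev)))
  if (is.null(el) || nrow(el) == 0L) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  }
  comp <- igraph::components(g)
  labels[idx] <- as.integer(comp$membership[seq_along(idx)])
  labels
}
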