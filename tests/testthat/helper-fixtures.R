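# Shared fixtures and independent oracles.  Every oracle here recomputes the
# quantity under test through a route the engines never take (igraph
# components, explicit interval enumeration), so engine bugs cannot cancel.

# Per-edge relative comparison at `tol`, with a small-value floor at 1e-6 of
# the map maximum: entries a million-fold below the map scale are compared in
# floored relative terms, since running-sum/score-subtraction arithmetic can
# only bound their error relative to the cluster score magnitude.
expect_rel_equal <- function(got, want, tol = 1e-9) {
  scale <- max(abs(want), 0)
  denom <- pmax(abs(want), scale * 1e-6, .Machine$double.xmin)
  expect_lt(max(abs(got - want) / denom, 0), tol)
}

k3_matrix <- function(stats = c(3, 2, 1)) {
  # triangle A-B = stats[1], B-C = stats[2], A-C = stats[3]
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- stats[1]
  m[2, 3] <- m[3, 2] <- stats[2]
  m[1, 3] <- m[3, 1] <- stats[3]
  stat_matrix(m)
}

random_stat_matrix <- function(n, seed, scale = 2) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n * n, sd = scale), n, n)
  })
  stat_matrix((a + t(a)) / 2)
}

# discretized TFCE by per-threshold component labeling through igraph
oracle_tfce_discrete <- function(m, E, H, dh) {
  ed <- matrix_to_edges(m)
  out <- numeric(nrow(ed))
  tmax <- max(ed$stat)
  if (tmax <= 0) return(edges_to_matrix(cbind(ed, tfce = out), n_rois(m), "tfce"))
  grid <- build_threshold_grid(tmax, dh)
  bins <- bin_index(ed$stat, dh)
  for (k in seq_len(grid$nth)) {
    act <- bins >= k
    if (!any(act)) next
    part <- clusters_at_threshold(ed[act, , drop = FALSE], h = 0 + .Machine$double.xmin)
    csize <- part$clusters$n_edges[match(part$edges$cluster, part$clusters$cluster)]
    out[act] <- out[act] + csize^E * grid$thresholds[k]^H * dh
  }
  ed$tfce <- out
  edges_to_matrix(ed, n_rois(m), "tfce")
}

# exact TFCE by explicit enumeration of every interval between consecutive
# sorted statistic values, recomputing components per interval
oracle_tfce_exact <- function(m, E, H) {
  ed <- matrix_to_edges(m)
  out <- numeric(nrow(ed))
  hs <- sort(unique(ed$stat[ed$stat > 0]))
  lower <- c(0, head(hs, -1))
  for (i in seq_along(hs)) {
    act <- ed$stat >= hs[i]
    if (!any(act)) next
    part <- clusters_at_threshold(ed[act, , drop = FALSE], h = .Machine$double.xmin)
    csize <- part$clusters$n_edges[match(part$edges$cluster, part$clusters$cluster)]
    out[act] <- out[act] + csize^E * interval_integral(lower[i], hs[i], H)
  }
  ed$tfce <- out
  edges_to_matrix(ed, n_rois(m), "tfce")
}

# brute-force voxel TFCE: threshold (shared bin rule) -> 3D labeling -> sum
oracle_tfce_voxel <- function(img, E, H, dh) {
  idx <- which(img$mask)
  stat <- img$stats[idx]
  out <- array(0, dim(img$stats))
  tmax <- max(stat)
  if (tmax <= 0) return(out)
  grid <- build_threshold_grid(tmax, dh)
  bins <- bin_index(stat, dh)
  for (k in seq_len(grid$nth)) {
    act <- bins >= k
    if (!any(act)) next
    sub <- array(FALSE, dim(img$stats))
    sub[idx[act]] <- TRUE
    lab <- voxel_clusters_reference(voxel_image(img$stats, sub, img$connectivity),
                                    h = min(stat[act]))
    labs <- lab$labels[idx[act]]
    csize <- lab$clusters$n_voxels
    out[idx[act]] <- out[idx[act]] + csize[labs]^E * grid$thresholds[k]^H * dh
  }
  out
}

# exact voxel TFCE by interval enumeration over sorted activation heights
oracle_tfce_exact_voxel <- function(img, E, H) {
  idx <- which(img$mask)
  stat <- img$stats[idx]
  out <- array(0, dim(img$stats))
  hs <- sort(unique(stat[stat > 0]))
  lower <- c(0, head(hs, -1))
  for (i in seq_along(hs)) {
    act <- stat >= hs[i]
    sub <- img$mask & array(FALSE, dim(img$stats))
    sub[idx[act]] <- TRUE
    lab <- voxel_clusters_reference(voxel_image(img$stats, sub, img$connectivity),
                                    h = hs[i])
    labs <- lab$labels[idx[act]]
    csize <- lab$clusters$n_voxels
    out[idx[act]] <- out[idx[act]] + csize[labs]^E * interval_integral(lower[i], hs[i], H)
  }
  out
}

# partition of active voxels through the min-weight graph construction
graph_voxel_partition <- function(vg, h) {
  act <- vg$nodes$stat >= h
  keep <- vg$edges$weight >= h
  sub <- vg$edges[keep, , drop = FALSE]
  ids <- which(act)
  g <- igraph::make_empty_graph(n = nrow(vg$nodes), directed = FALSE)
  if (nrow(sub)) g <- igraph::add_edges(g, rbind(sub$u, sub$v))
  comp <- igraph::components(g)$membership[ids]
  split(vg$index[ids], comp)
}

# partition of active voxels straight from the labeled volume
reference_voxel_partition <- function(img, h) {
  lab <- voxel_clusters_reference(img, h)
  idx <- which(lab$labels > 0)
  split(idx, lab$labels[idx])
}

same_partition <- function(a, b) {
  norm <- function(p) {
    p <- lapply(p, sort)
    unname(p[order(vapply(p, min, 1))])
  }
  identical(norm(a), norm(b))
}
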