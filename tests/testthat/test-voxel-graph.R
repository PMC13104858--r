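strip_image <- function(stats = c(2, 5, 3, 0.5), mask = NULL, connectivity = 6) {
  voxel_image(array(stats, c(length(stats), 1, 1)), mask = mask,
              connectivity = connectivity)
}

test_that("voxel-to-graph conversion takes pairwise minima over adjacency", {
  g <- voxel_to_graph(strip_image(c(2, 5, 3)))
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(g$edges$u, c(1L, 2L))
  expect_equal(g$edges$v, c(2L, 3L))
  expect_equal(g$edges$weight, c(2, 3))
  expect_true(all(g$edges$weight <= g$nodes$stat[g$edges$u]))
  expect_true(all(g$edges$weight <= g$nodes$stat[g$edges$v]))

  # masking out the middle voxel leaves the ends non-adjacent
  mk <- array(c(TRUE, FALSE, TRUE), c(3, 1, 1))
  gm <- voxel_to_graph(strip_image(c(2, 5, 3), mask = mk))
  expect_equal(nrow(gm$edges), 0L)
  expect_equal(nrow(gm$nodes), 2L)

  # empty mask: empty graph
  ge <- voxel_to_graph(strip_image(c(1, 1, 1), mask = array(FALSE, c(3, 1, 1))))
  expect_equal(nrow(ge$nodes), 0L)
})

test_that("voxel degrees respect the 6/18/26 connectivity bounds", {
  img <- function(conn) voxel_image(array(1, c(3, 3, 3)), connectivity = conn)
  for (conn in c(6, 18, 26)) {
    g <- voxel_to_graph(img(conn))
    deg <- tabulate(c(g$edges$u, g$edges$v), nbins = 27)
    expect_lte(max(deg), conn)
    center <- g$nodes$node[g$nodes$x == 2 & g$nodes$y == 2 & g$nodes$z == 2]
    expect_equal(deg[center], conn)       # interior voxel hits the bound
    expect_equal(nrow(g$edges), sum(deg) / 2)
  }
})

test_that("graph clusters equal 3D connected-component labels voxel for voxel", {
  for (conn in c(6, 18, 26)) {
    img <- synth_voxel_image(c(8, 7, 6), n_blobs = 3, blob_sigma = 1.5,
                             peak = 4, noise_sd = 0.8, connectivity = conn,
                             seed = conn)
    vg <- voxel_to_graph(img)
    hs <- quantile(img$stats[img$stats > 0], seq(0.1, 0.95, length.out = 8))
    for (h in hs) {
      expect_true(same_partition(graph_voxel_partition(vg, h),
                                 reference_voxel_partition(img, h)))
    }
  }
})

test_that("incremental voxel TFCE matches the threshold-label-sum brute force", {
  # hand value: stat-5 voxel in [2, 5, 3, 0.5] has c = 3,3,2,1,1 at h = 1..5
  tf <- tfce_voxel(strip_image(), E = 1, H = 1, dh = 1)
  expect_equal(tf[2, 1, 1], 24)
  expect_equal(tf[4, 1, 1], 0)     # below dh

  for (conn in c(6, 26)) {
    img <- synth_voxel_image(c(7, 6, 5), n_blobs = 2, blob_sigma = 1.2,
                             peak = 3, noise_sd = 0.6, connectivity = conn,
                             seed = 10 + conn)
    got <- tfce_voxel(img, E = 0.5, H = 2, dh = 0.2)
    want <- oracle_tfce_voxel(img, E = 0.5, H = 2, dh = 0.2)
    expect_rel_equal(got, want)
    # in-package reference engine takes the same brute-force route
    expect_equal(array(tfce_voxel(img, E = 0.5, H = 2, dh = 0.2,
                                  method = "reference"), dim(want)),
                 want, tolerance = 1e-12)
  }
})

test_that("isolated supra-threshold voxels behave as singleton clusters", {
  # two active voxels separated by a sub-threshold one
  img <- strip_image(c(3, 0.2, 2.5))
  lab <- voxel_clusters_reference(img, h = 1)
  expect_equal(nrow(lab$clusters), 2L)
  expect_equal(lab$clusters$n_voxels, c(1L, 1L))

  # strip example: h = 3 keeps voxels 2 and 3 as one component
  lab3 <- voxel_clusters_reference(strip_image(), h = 3)
  expect_equal(nrow(lab3$clusters), 1L)
  expect_equal(sort(which(lab3$labels > 0)), c(2L, 3L))
  expect_equal(nrow(voxel_clusters_reference(strip_image(), h = 99)$clusters), 0L)

  # singleton closed form: TFCE -> t^(H+1)/(H+1) as dh -> 0
  lone <- voxel_image(array(c(2, 0, 0), c(3, 1, 1)))
  tf <- tfce_voxel(lone, E = 0.5, H = 2, dh = 0.001)
  expect_equal(tf[1, 1, 1], 2^3 / 3, tolerance = 1e-2)
  # and exactly under the exact engine
  tfx <- tfce_voxel(lone, E = 0.5, H = 2, method = "exact")
  expect_equal(tfx[1, 1, 1], 2^3 / 3)
})

test_that("exact TFCE on the voxel graph equals interval enumeration", {
  img <- synth_voxel_image(c(6, 5, 4), n_blobs = 2, blob_sigma = 1, peak = 3,
                           noise_sd = 0.5, connectivity = 26, seed = 4)
  got <- tfce_voxel(img, E = 0.5, H = 2, method = "exact")
  want <- oracle_tfce_exact_voxel(img, E = 0.5, H = 2)
  expect_rel_equal(got, want)
})

test_that("volumes with no positive statistics give all-zero TFCE", {
  img <- voxel_image(array(-abs(rnorm(60)), c(5, 4, 3)))
  expect_true(all(tfce_voxel(img, dh = 0.1) == 0))
  expect_true(all(tfce_voxel(img, method = "exact") == 0))
})
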