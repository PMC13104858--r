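test_that("incremental engine equals the reference engine edge for edge", {
  # a reduced sweep of the full equivalence suite (the acceptance test runs
  # the complete grid)
  for (n in c(10, 30)) {
    for (dh in c(0.05, 0.25)) {
      m <- synth_stat_matrix(n, seed = n + round(100 * dh))
      a <- tfce_fc(m, E = 0.4, H = 3, dh = dh, method = "reference")
      b <- tfce_fc(m, E = 0.4, H = 3, dh = dh, method = "incremental")
      expect_rel_equal(b, unclass(a))
    }
  }
  expect_equal(unclass(tfce_fc(k3_matrix(), E = 1, H = 1, dh = 1)),
               unclass(tfce_fc(k3_matrix(), E = 1, H = 1, dh = 1,
                               method = "reference")),
               ignore_attr = TRUE)
})

test_that("descending incremental pass records the hand-simulated S structure", {
  st <- ic_tfce_state(k3_matrix(c(3, 2, 1)), E = 1, H = 1, dh = 1)
  # bin 3: only edge A-B alive -> cluster of 1 edge on nodes 1, 2
  expect_equal(st$S[3, ], c(1L, 1L, 0L))
  # bin 2: edge B-C joins -> all three nodes, 2 edges
  expect_equal(st$S[2, ], c(2L, 2L, 2L))
  # bin 1: triangle complete
  expect_equal(st$S[1, ], c(3L, 3L, 3L))

  # single edge stat 2.0, dh = 1: S identical at both thresholds
  m1 <- stat_matrix(matrix(c(0, 2, 2, 0), 2, 2))
  s1 <- ic_tfce_state(m1, E = 1, H = 1, dh = 1)
  expect_equal(s1$S, matrix(1L, 2, 2), ignore_attr = TRUE)

  # N = 4 path graph: every edge merges two distinct clusters
  mp <- matrix(0, 4, 4)
  mp[1, 2] <- mp[2, 1] <- 3; mp[2, 3] <- mp[3, 2] <- 2; mp[3, 4] <- mp[4, 3] <- 1
  sp <- ic_tfce_state(stat_matrix(mp), E = 1, H = 1, dh = 1)
  expect_identical(sp$merges, 3L)
})

test_that("cumulative accumulator follows F[k] = F[k-1] + S[k]^E (k dh)^H dh", {
  st <- ic_tfce_state(k3_matrix(c(3, 2, 1)), E = 1, H = 1, dh = 1)
  expect_equal(st$F[, 1], c(3, 7, 10))          # three-term cumulative sum
  # direct recomputation from S for arbitrary exponents
  st2 <- ic_tfce_state(random_stat_matrix(9, seed = 5), E = 0.4, H = 3, dh = 0.2)
  S <- st2$S
  w <- (seq_len(nrow(S)) * 0.2)^3 * 0.2
  Fwant <- apply(ifelse(S > 0, S^0.4, 0) * w, 2, cumsum)
  expect_equal(st2$F, Fwant, ignore_attr = TRUE, tolerance = 1e-12)

  # unit cluster: a lone edge accumulates sum (k dh)^H dh regardless of E;
  # nth = ceiling(1.7/0.5) = 4, and the topmost (empty) bin adds nothing
  m1 <- stat_matrix(matrix(c(0, 1.7, 1.7, 0), 2, 2))
  s1 <- ic_tfce_state(m1, E = 0.123, H = 2, dh = 0.5)
  expect_equal(s1$F[, 1], cumsum(c((c(1, 2, 3) * 0.5)^2 * 0.5, 0)))
})

test_that("edges retrieve their value at the bin row through either endpoint", {
  st <- ic_tfce_state(k3_matrix(c(3, 2, 1)), E = 1, H = 1, dh = 1)
  expect_equal(lookup_edge(st, 1, 2), 10)       # stat 3, bin 3, endpoint A
  expect_equal(lookup_edge(st, 2, 3), 7)        # stat 2, bin 2
  expect_equal(st$F[2, 2], st$F[2, 3])          # endpoint symmetry

  m <- stat_matrix(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  expect_equal(lookup_edge(ic_tfce_state(m, dh = 0.5), 1, 2), 0)  # bin 0

  # exact endpoint symmetry on random inputs
  for (seed in 1:4) {
    st <- ic_tfce_state(random_stat_matrix(15, seed = 30 + seed),
                        E = 0.4, H = 3, dh = 0.1)
    ed <- st$edges[st$edges$bin >= 1, ]
    expect_identical(st$F[cbind(ed$bin, ed$u)], st$F[cbind(ed$bin, ed$v)])
    expect_equal(ed$tfce, st$F[cbind(ed$bin, ed$u)])
  }
})

test_that("merge count stays below N and clusters only grow as thresholds fall", {
  for (seed in 1:5) {
    n <- sample(6:25, 1)
    st <- ic_tfce_state(random_stat_matrix(n, seed = 60 + seed),
                        E = 0.5, H = 2, dh = 0.2)
    expect_lte(st$merges, n - 1)
    if (nrow(st$S) > 1)
      expect_true(all(diff(st$S) <= 0L))  # S non-increasing in k: lower k = bigger
  }
  # fully connected positive matrix: exactly N - 1 merges
  full <- stat_matrix(matrix(1, 7, 7) - diag(1, 7) + diag(0, 7))
  expect_identical(ic_tfce_state(full, dh = 0.5)$merges, 6L)
})

test_that("maps with no supra-threshold edge come back all zero", {
  neg <- stat_matrix(-abs(random_stat_matrix(6, seed = 9)) - 0.1 +
                       diag(0.1, 6), tol = 1e-8)
  expect_true(all(tfce_fc(neg, dh = 0.1) == 0))
  st <- ic_tfce_state(neg, dh = 0.1)
  expect_identical(st$merges, 0L)
  expect_equal(nrow(st$S), 0L)
})

test_that("the accumulator refuses to exceed its memory budget", {
  m <- random_stat_matrix(40, seed = 2)
  expect_error(tfce_fc(m, dh = 0.001, max_cells = 1000), "max_cells")
  # and the same input succeeds with the default budget
  expect_silent(tfce_fc(m, dh = 0.01))
})
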