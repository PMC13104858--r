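toy_dataset <- function() {
  # 2+2 subjects, 3 ROIs; the 1-2 edge carries the group difference
  mk <- function(e12, e13, e23) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- e12; m[1, 3] <- m[3, 1] <- e13
    m[2, 3] <- m[3, 2] <- e23
    m
  }
  group_dataset(list(mk(1, 0.3, -0.2), mk(2, 0.1, 0.4),
                     mk(4, 0.2, 0.1), mk(6, -0.1, 0.2)),
                group = c(1, 1, 2, 2))
}

test_that("edgewise t statistics match t.test on every edge", {
  d <- toy_dataset()
  ts <- group_tstats(d)
  # hand pooled t at the 1-2 edge: means 1.5 vs 5, variances 0.5 and 2
  expect_equal(ts[1, 2], (5 - 1.5) / sqrt(1.25 * (1 / 2 + 1 / 2)))
  for (j in seq_len(ncol(d$x))) {
    want <- t.test(d$x[d$group == 2, j], d$x[d$group == 1, j],
                   var.equal = TRUE)$statistic
    expect_equal(ts[d$edges$u[j], d$edges$v[j]], unname(want))
  }

  # one-sample design against zero
  d1 <- group_dataset(d$x, group = NULL, n_rois = 3)
  t1 <- group_tstats(d1)
  for (j in seq_len(ncol(d1$x)))
    expect_equal(t1[d1$edges$u[j], d1$edges$v[j]],
                 unname(t.test(d1$x[, j])$statistic))
})

test_that("zero-variance edges get statistic zero with a warning", {
  d <- toy_dataset()
  d$x[, 2] <- 1   # constant across every subject
  expect_warning(ts <- group_tstats(d), "zero-variance")
  expect_equal(ts[1, 3], 0)
})

test_that("null two-group t values are centred on zero", {
  d <- synth_group_dataset(20, 46, effect_size = 0, seed = 99)  # 1035 edges
  ts <- matrix_to_edges(group_tstats(d))$stat
  expect_lt(abs(mean(ts)), 0.1)
})

test_that("group_dataset enforces its design invariants", {
  m <- lapply(1:3, function(i) matrix(0, 3, 3))
  expect_error(group_dataset(m, group = c(1, 1, 2)), "at least 4",
               class = "ictfce_bad_params")
  m4 <- lapply(1:4, function(i) matrix(rnorm(1) * diag(0, 3), 3, 3))
  expect_error(group_dataset(m4, group = c(1, 1, 1, 2)), "at least 2",
               class = "ictfce_bad_params")
  expect_error(synth_group_dataset(1, 5), class = "ictfce_bad_params")
  expect_error(synth_group_dataset(10, 5,
                                   effect_edges = tibble::tibble(u = 2, v = 2)),
               class = "ictfce_bad_params")
})

test_that("permutation p-values are valid, bounded and monotone in TFCE", {
  d <- synth_group_dataset(10, 12, effect_nodes = 1:4, effect_size = 1.5,
                           seed = 5)
  pt <- permutation_test(d, dh = 0.25, n_perm = 50, seed = 7)
  p <- pt$edges$p_fwer
  expect_true(all(p >= 1 / 51) && all(p <= 1))
  expect_equal(p[pt$edges$tfce == 0], rep(1, sum(pt$edges$tfce == 0)))
  ord <- order(pt$edges$tfce)
  expect_true(all(diff(p[ord]) <= 1e-15))   # higher TFCE never raises p

  # determinism and engine equivalence under a shared seed
  pt2 <- permutation_test(d, dh = 0.25, n_perm = 50, seed = 7)
  expect_identical(tidy(pt), tidy(pt2))
  ptr <- permutation_test(d, dh = 0.25, n_perm = 50, seed = 7,
                          engine = "reference")
  expect_equal(tidy(pt), tidy(ptr))
  expect_equal(pt$null_max, ptr$null_max)
})

test_that("two-sided inference doubles the smaller one-tailed p-value", {
  d <- synth_group_dataset(8, 10, effect_nodes = 1:3, effect_size = 1, seed = 11)
  pp <- permutation_test(d, dh = 0.25, n_perm = 40, seed = 3, tails = "pos")
  pb <- permutation_test(d, dh = 0.25, n_perm = 40, seed = 3, tails = "both")
  expect_true(all(pb$edges$p_fwer >= pp$edges$p_fwer - 1e-15))
  expect_true(all(pb$edges$p_fwer <= 1))

  # one-sample sign-flip path runs and keeps p valid
  d1 <- group_dataset(d$x, group = NULL, n_rois = 10)
  p1 <- permutation_test(d1, dh = 0.25, n_perm = 30, seed = 2)
  expect_true(all(p1$edges$p_fwer >= 1 / 31 & p1$edges$p_fwer <= 1))
})

test_that("exhausted relabelings trigger a replacement-sampling warning", {
  d <- synth_group_dataset(2, 5, seed = 1)      # choose(4, 2) = 6 relabelings
  expect_warning(permutation_test(d, dh = 0.25, n_perm = 10, seed = 1),
                 "distinct relabelings")
})

test_that("power estimation shares subject and permutation draws across dh", {
  pw <- estimate_power(n_sub = 8, n_rois = 10, effect_nodes = 1:4,
                       effect_size = 1.5, dh = c(0.2, 0.2), n_reps = 4,
                       n_perm = 30, seed = 13)
  pe <- tidy(pw)
  half <- nrow(pe) / 2
  # identical dh on identical draws: identical rejection frequencies
  expect_equal(pe$power[seq_len(half)], pe$power[half + seq_len(half)])
  expect_true(all(pe$power >= 0 & pe$power <= 1))
})

test_that("per-network power ranks networks by mean rejection frequency", {
  nets <- rep(c("A", "B"), each = 5)
  pw <- estimate_power(n_sub = 8, n_rois = 10, effect_nodes = 1:5,
                       effect_size = 2, dh = 0.25, n_reps = 4, n_perm = 30,
                       seed = 17, networks = nets)
  pn <- pw$per_network
  expect_setequal(unique(pn$network), c("A-A", "A-B", "B-B"))
  expect_equal(sum(pn$n_edges), 45)
  top <- top_networks(pw, n = 1)
  expect_equal(top$network, "A-A")   # the planted block
})
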