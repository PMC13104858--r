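#' Group FC dataset
#'
#' Holds per-subject FC values in subject-by-edge form together with the
#' group design: two-sample (two group labels) or one-sample (all subjects
#' in one group, tested against zero).
#'
#' @param subjects Either a list of per-subject symmetric `N x N` matrices,
#'   or a numeric `n_sub x n_edges` matrix of edge values in
#'   [matrix_to_edges()] order (then `n_rois` is required).
#' @param group Integer/factor group labels (`NULL` or constant for
#'   one-sample).
#' @param n_rois Number of ROIs (required for matrix input).
#' @param edges Optional edge tibble (`u`, `v`) matching the columns.
#' @param effect_edges Optional integer indices of planted-effect edges
#'   (carried through for power bookkeeping).
#' @return A list of class `group_dataset` with `x` (subject x edge matrix),
#'   `group`, `design`, `n_rois`, `edges`, `effect_edges`.
#' @export
group_dataset <- function(subjects, group = NULL, n_rois = NULL, edges = NULL,
                          effect_edges = NULL) {
  if (is.list(subjects) && !is.matrix(subjects)) {
    mats <- lapply(subjects, as_stat_matrix)
    n_rois <- n_rois %||% nrow(mats[[1]])
    if (!all(vapply(mats, nrow, 1L) == n_rois))
      abort("all subject matrices must share one parcellation",
            class = "ictfce_bad_params")
    edges <- matrix_to_edges(mats[[1]])[c("u", "v")]
    x <- do.call(rbind, lapply(mats, function(m) matrix_to_edges(m)$stat))
  } else {
    x <- as.matrix(subjects)
    if (is.null(n_rois)) abort("`n_rois` is required for matrix input",
                               class = "ictfce_bad_params")
    if (is.null(edges))
      edges <- matrix_to_edges(stat_matrix(matrix(0, n_rois, n_rois)))[c("u", "v")]
    if (ncol(x) != nrow(edges))
      abort("subject matrix has wrong number of edge columns",
            class = "ictfce_bad_params")
  }
  n_sub <- nrow(x)
  if (n_sub < 4L) abort("need at least 4 subjects", class = "ictfce_bad_params")
  if (is.null(group)) group <- rep(1L, n_sub)
  group <- as.integer(factor(group))
  if (length(group) != n_sub)
    abort("`group` must have one label per subject", class = "ictfce_bad_params")
  ng <- length(unique(group))
  design <- if (ng == 1L) "one_sample" else "two_sample"
  if (ng > 2L) abort("at most two groups are supported", class = "ictfce_bad_params")
  if (design == "two_sample" && min(table(group)) < 2L)
    abort("each group needs at least 2 subjects", class = "ictfce_bad_params")
  structure(list(x = x, group = group, design = design, n_rois = n_rois,
                 edges = edges, effect_edges = effect_edges),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("<group_dataset> %d subjects (%s), %d ROIs, %d edges\n",
              nrow(x$x), x$design, x$n_rois, ncol(x$x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized edgewise t statistics; zero-variance edges -> 0 (warned once)
edge_tstats <- function(x, group, design) {
  n <- nrow(x)
  if (design == "two_sample") {
    a <- group == 1L
    na <- sum(a); nb <- n - na
    ma <- colMeans(x[a, , drop = FALSE])
    mb <- colMeans(x[!a, , drop = FALSE])
    va <- (colSums(x[a, , drop = FALSE]^2) - na * ma^2) / (na - 1)
    vb <- (colSums(x[!a, , drop = FALSE]^2) - nb * mb^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    t <- (mb - ma) / se
  } else {
    m <- colMeans(x)
    s <- sqrt(pmax(0, (colSums(x^2) - n * m^2) / (n - 1)))
    se <- s / sqrt(n)
    t <- m / se
  }
  bad <- !is.finite(t)
  if (any(bad)) {
    warn(sprintf("%d zero-variance edge(s); statistic set to 0", sum(bad)))
    t[bad] <- 0
  }
  t
}

#' Edgewise group t statistics
#'
#' Two-sample pooled-variance t statistics (group 2 minus group 1) or
#' one-sample t against zero, per edge.  Edges with zero variance get
#' statistic 0 with a warning.
#'
#' @param d A [group_dataset()].
#' @return A [stat_matrix()] of t values.
#' @export
group_tstats <- function(d) {
  stopifnot(inherits(d, "group_dataset"))
  t <- edge_tstats(d$x, d$group, d$design)
  ed <- d$edges
  ed$stat <- t
  stat_matrix(edges_to_matrix(ed, d$n_rois, "stat"))
}

# TFCE of an edge-statistic vector without the matrix round trip
tfce_edge_vector <- function(stat, u0, v0, n, E, H, dh, engine, max_cells = 1e8) {
  switch(engine,
         incremental = cpp_tfce_ic(n, u0, v0, stat, E, H, dh, FALSE, max_cells)$tfce,
         reference = cpp_tfce_reference(n, u0, v0, stat, E, H, dh),
         exact = cpp_tfce_exact_fc(n, u0, v0, stat, E, H))
}

#' Max-statistic permutation test with TFCE enhancement
#'
#' Computes the observed TFCE map, builds a null distribution of the global
#' maximum TFCE over `n_perm` random relabelings (two-sample: group-label
#' shuffles; one-sample: random sign flips), and returns familywise-error
#' corrected p-values
#' \deqn{p(e) = (1 + \#\{perm : \max TFCE_{perm} \ge TFCE_{obs}(e)\}) / (n_{perm} + 1),}
#' never zero by construction.  Every permutation's TFCE recomputes its own
#' `tmax` (hence its own number of threshold steps) from the permuted map.
#' `tails = "both"` runs the positive and negative tails separately and
#' Bonferroni-doubles the smaller p-value.
#'
#' @param d A [group_dataset()].
#' @param E,H,dh TFCE parameters ([tfce_fc()]); `dh` is ignored by the exact
#'   engine.
#' @param engine `"incremental"`, `"reference"` or `"exact"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; fixed seeds give identical permutation
#'   sequences for every engine.
#' @param alpha Nominal FWER level recorded on the result.
#' @param tails `"pos"` (default), `"neg"` or `"both"`.
#' @return An object of class `tfce_perm`; see [tidy.tfce_perm()].
#' @export
permutation_test <- function(d, E = 0.4, H = 3, dh = 0.1,
                             engine = c("incremental", "reference", "exact"),
                             n_perm = 1000, seed = 1, alpha = 0.05,
                             tails = c("pos", "neg", "both")) {
  engine <- match.arg(engine)
  tails <- match.arg(tails)
  stopifnot(inherits(d, "group_dataset"), n_perm >= 1)
  n_sub <- nrow(d$x)
  n_distinct <- if (d$design == "two_sample")
    choose(n_sub, sum(d$group == 1L)) else 2^n_sub
  if (n_perm > n_distinct)
    warn(sprintf("n_perm = %d exceeds the %g distinct relabelings; sampling with replacement",
                 n_perm, n_distinct))
  u0 <- d$edges$u - 1L
  v0 <- d$edges$v - 1L
  perms <- withr::with_seed(seed, {
    if (d$design == "two_sample")
      replicate(n_perm, sample(d$group))
    else
      replicate(n_perm, sample(c(-1, 1), n_sub, replace = TRUE))
  })

  one_tail <- function(sign) {
    t_obs <- sign * edge_tstats(d$x, d$group, d$design)
    tfce_obs <- tfce_edge_vector(t_obs, u0, v0, d$n_rois, E, H, dh, engine)
    null_max <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      if (d$design == "two_sample") {
        tp <- sign * edge_tstats(d$x, perms[, p], d$design)
      } else {
        tp <- sign * edge_tstats(d$x * perms[, p], d$group, d$design)
      }
      tf <- tfce_edge_vector(tp, u0, v0, d$n_rois, E, H, dh, engine)
      null_max[p] <- if (length(tf)) max(tf, 0) else 0
    }
    s <- sort(null_max)
    cnt_ge <- n_perm - findInterval(tfce_obs, s, left.open = TRUE)
    list(t = t_obs, tfce = tfce_obs, p = (1 + cnt_ge) / (n_perm + 1),
         null_max = null_max)
  }

  pos <- if (tails %in% c("pos", "both")) one_tail(1) else NULL
  neg <- if (tails %in% c("neg", "both")) one_tail(-1) else NULL
  main <- pos %||% neg
  p <- switch(tails,
              pos = pos$p, neg = neg$p,
              both = pmin(1, 2 * pmin(pos$p, neg$p)))
  ed <- d$edges
  ed$stat <- if (tails == "neg") -main$t else main$t
  ed$tfce <- main$tfce
  ed$p_fwer <- p
  structure(list(edges = ed, null_max = main$null_max,
                 null_max_neg = if (tails == "both") neg$null_max else NULL,
                 params = tfce_params(E, H, if (engine == "exact") NULL else dh),
                 engine = engine, n_perm = n_perm, seed = seed, alpha = alpha,
                 tails = tails, design = d$design, n_rois = d$n_rois),
            class = "tfce_perm")
}

#' @export
print.tfce_perm <- function(x, ...) {
  cat(sprintf("<tfce_perm> %s, %d ROIs, %d perms (%s tail), %d/%d edges with p <= %.3g\n",
              x$engine, x$n_rois, x$n_perm, x$tails,
              sum(x$edges$p_fwer <= x$alpha), nrow(x$edges), x$alpha))
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x A `tfce_perm` object.
#' @param ... Unused.
#' @return One row per edge: `u`, `v`, `stat`, `tfce`, `p_fwer`.
#' @export
tidy.tfce_perm <- function(x, ...) as_tibble(x$edges)

#' @rdname tidy.tfce_perm
#' @export
glance.tfce_perm <- function(x, ...) {
  tibble(n_rois = x$n_rois, n_edges = nrow(x$edges), n_perm = x$n_perm,
         engine = x$engine, tails = x$tails, alpha = x$alpha,
         n_significant = sum(x$edges$p_fwer <= x$alpha),
         max_tfce = max(x$edges$tfce),
         null_max_q95 = unname(stats::quantile(x$null_max, 0.95)))
}

#' Empirical power of TFCE permutation inference
#'
#' Repeats data generation ([synth_group_dataset()]) and permutation testing
#' `n_reps` times and reports per-edge rejection frequencies.  When several
#' `dh` values are supplied they are compared on identical subject draws and
#' identical permutation sequences within each repetition, so between-`dh`
#' differences are estimated without simulation noise from the data.  With
#' 100 repetitions the binomial standard error of any power estimate is at
#' most `sqrt(0.25 / 100) = 0.05`.
#'
#' @param n_sub,n_rois,effect_nodes,effect_size,noise_sd,design Generator
#'   settings, see [synth_group_dataset()].
#' @param dh Vector of step sizes to compare.
#' @param E,H TFCE exponents.
#' @param engine TFCE engine.
#' @param n_reps Number of repetitions.
#' @param alpha FWER level for rejection.
#' @param n_perm Permutations per test.
#' @param seed Master seed; spawns one reproducible stream per repetition.
#' @param networks Optional length-`n_rois` node-to-network labeling; edges
#'   are grouped by their unordered network pair.
#' @return An object of class `tfce_power` with per-edge, overall and (if
#'   `networks` given) per-network mean power.
#' @export
estimate_power <- function(n_sub, n_rois, effect_nodes = NULL, effect_size = 0.5,
                           noise_sd = 1, design = "two_sample",
                           dh = 0.1, E = 0.4, H = 3,
                           engine = "incremental", n_reps = 100, alpha = 0.05,
                           n_perm = 200, seed = 1, networks = NULL) {
  stopifnot(n_reps >= 1)
  seeds <- withr::with_seed(seed, {
    matrix(sample.int(2^31 - 2, 2 * n_reps), n_reps, 2)
  })
  rej <- NULL
  eff_idx <- integer()
  edges <- NULL
  for (r in seq_len(n_reps)) {
    d <- synth_group_dataset(n_sub, n_rois, effect_nodes = effect_nodes,
                             effect_size = effect_size, noise_sd = noise_sd,
                             design = design, seed = seeds[r, 1])
    if (is.null(rej)) {
      edges <- d$edges
      eff_idx <- d$effect_edges
      rej <- array(0, c(length(dh), nrow(edges)))
    }
    for (j in seq_along(dh)) {
      pt <- permutation_test(d, E = E, H = H, dh = dh[j], engine = engine,
                             n_perm = n_perm, seed = seeds[r, 2], alpha = alpha)
      rej[j, ] <- rej[j, ] + (pt$edges$p_fwer <= alpha)
    }
  }
  power <- rej / n_reps
  per_edge <- tidyr::expand_grid(dh = dh, edge = seq_len(nrow(edges)))
  per_edge <- dplyr::mutate(per_edge,
                            u = edges$u[.data$edge], v = edges$v[.data$edge],
                            power = as.numeric(t(power))[seq_len(nrow(per_edge))],
                            effect = .data$edge %in% eff_idx)
  per_edge <- dplyr::select(per_edge, "dh", "u", "v", "power", "effect")
  overall <- dplyr::summarise(dplyr::group_by(per_edge, dh = .data$dh),
                              overall_power = mean(.data$power),
                              effect_power = if (any(.data$effect))
                                mean(.data$power[.data$effect]) else NA_real_,
                              .groups = "drop")
  per_network <- NULL
  if (!is.null(networks)) {
    stopifnot(length(networks) == n_rois)
    lab <- purrr::map2_chr(networks[per_edge$u], networks[per_edge$v],
                           ~ paste(sort(c(.x, .y)), collapse = "-"))
    per_network <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(per_edge, network = lab),
                      .data$dh, .data$network),
      power = mean(.data$power), n_edges = dplyr::n(), .groups = "drop")
    per_network <- dplyr::arrange(per_network, .data$dh, dplyr::desc(.data$power))
  }
  structure(list(per_edge = per_edge, overall = overall,
                 per_network = per_network,
                 config = list(n_sub = n_sub, n_rois = n_rois,
                               effect_nodes = effect_nodes,
                               effect_size = effect_size, noise_sd = noise_sd,
                               design = design, dh = dh, E = E, H = H,
                               engine = engine, n_reps = n_reps, alpha = alpha,
                               n_perm = n_perm, seed = seed)),
            class = "tfce_power")
}

#' @export
print.tfce_power <- function(x, ...) {
  cat(sprintf("<tfce_power> %d reps, %d perms, alpha %.3g\n",
              x$config$n_reps, x$config$n_perm, x$config$alpha))
  print(x$overall)
  invisible(x)
}

#' Tidy a power-analysis result
#'
#' @param x A `tfce_power` object.
#' @param ... Unused.
#' @return `tidy()`: one row per (dh, edge) with rejection frequency and the
#'   planted-effect flag; `glance()`: one row per dh with overall mean power
#'   and mean power over the planted edges.
#' @export
tidy.tfce_power <- function(x, ...) x$per_edge

#' @rdname tidy.tfce_power
#' @export
glance.tfce_power <- function(x, ...) x$overall

#' Top-ranked networks by mean power
#'
#' @param x A `tfce_power` fitted with `networks`.
#' @param n How many networks to keep per dh.
#' @return Per-network mean power, ranked descending within each dh.
#' @export
top_networks <- function(x, n = 3) {
  stopifnot(inherits(x, "tfce_power"))
  if (is.null(x$per_network))
    abort("fit estimate_power() with `networks` to rank networks",
          class = "ictfce_bad_params")
  dplyr::slice_head(dplyr::group_by(x$per_network, .data$dh), n = n)
}
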