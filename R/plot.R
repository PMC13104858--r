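#' Plot a TFCE map as an edge heatmap
#'
#' @param object A `tfce_map` from [tfce_fc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfce_map <- function(object, ...) {
  ed <- as_tibble(object)
  ggplot2::ggplot(dplyr::bind_rows(ed, dplyr::rename(ed, u = "v", v = "u")),
                  ggplot2::aes(x = .data$v, y = .data$u, fill = .data$tfce)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "TFCE") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "ROI", y = "ROI",
                  title = sprintf("TFCE map (%s engine)", attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null distribution
#'
#' Histogram of the per-permutation maximum TFCE with the observed map
#' maximum and the level-`alpha` critical value marked.
#'
#' @param object A `tfce_perm` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfce_perm <- function(object, ...) {
  crit <- stats::quantile(object$null_max, 1 - object$alpha)
  ggplot2::ggplot(tibble(max_tfce = object$null_max),
                  ggplot2::aes(x = .data$max_tfce)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = max(object$edges$tfce),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = crit, linetype = "dashed") +
    ggplot2::labs(x = "max TFCE per permutation", y = "count",
                  title = sprintf("Null of the maximum TFCE (%d permutations)",
                                  object$n_perm),
                  subtitle = "solid: observed maximum; dashed: critical value") +
    ggplot2::theme_minimal()
}

#' Plot estimated power
#'
#' Mean power over the planted-effect edges (and overall, dotted) per `dh`.
#'
#' @param object A `tfce_power` from [estimate_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfce_power <- function(object, ...) {
  ov <- object$overall
  ggplot2::ggplot(ov, ggplot2::aes(x = factor(.data$dh))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$effect_power), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$overall_power)) +
    ggplot2::labs(x = "dh", y = "power",
                  title = "Empirical power at planted-effect edges",
                  subtitle = "points: overall mean power across all edges") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
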