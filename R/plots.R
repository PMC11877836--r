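#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a methylation metaprofile
#'
#' Line plot of pooled fractional methylation per bin, one line per context.
#'
#' @param object A `meta_profile` tibble from [ends_metaprofile()] or
#'   [flank_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_profile <- function(object, ...) {
  x <- if ("bin_start" %in% names(object)) "bin_start" else "bin_index"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x]], y = .data$fraction,
                               colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = if (x == "bin_start") "distance from anchor (bp)" else "bin",
                  y = "fractional methylation", colour = "context") +
    ggplot2::theme_minimal()
}

#' Plot called loci by label and length
#'
#' @param object An `slm_result`.
#' @param ... Unused.
#' @return A ggplot histogram of locus lengths, faceted by label.
#' @export
autoplot.slm_result <- function(object, ...) {
  ggplot2::ggplot(object$loci,
                  ggplot2::aes(x = .data$length, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::labs(x = "locus length (bp)", y = "loci", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of DMR windows
#'
#' @param object A `dmr_result`.
#' @param ... Unused.
#' @return A ggplot of percent methylation difference against -log10 q.
#' @export
autoplot.dmr_result <- function(object, ...) {
  w <- object$windows
  w$called <- w$qvalue < object$params$q_max &
    abs(w$meth_diff) * 100 > object$params$min_diff
  ggplot2::ggplot(w, ggplot2::aes(x = 100 * .data$meth_diff,
                                  y = -log10(pmax(.data$qvalue, 1e-300)),
                                  colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "methylation difference (percentage points)",
                  y = expression(-log[10] ~ q), colour = "DMR") +
    ggplot2::theme_minimal()
}

#' Stacked-bar view of locus proximity classes
#'
#' @param summary Output of [proximity_summary()].
#' @return A ggplot, one bar per feature kind.
#' @export
plot_proximity <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$kind, y = .data$percent,
                                        fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(overlapping = "#4daf4a",
                                          within_near = "#ffd92f",
                                          beyond_near = "#377eb8")) +
    ggplot2::labs(x = NULL, y = "% of loci", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Expression-pattern heatmap of clustered transposons
#'
#' @param object A `te_clusters` from [cluster_active()].
#' @param ... Unused.
#' @return A ggplot tile heatmap of z-scores, rows ordered by cluster.
#' @export
autoplot.te_clusters <- function(object, ...) {
  z <- object$zscores %>%
    dplyr::left_join(object$labels, by = "te_id") %>%
    dplyr::arrange(.data$cluster) %>%
    dplyr::mutate(row = dplyr::row_number()) %>%
    tidyr::pivot_longer(-c("te_id", "cluster", "row"),
                        names_to = "group", values_to = "z")
  ggplot2::ggplot(z, ggplot2::aes(x = .data$group, y = .data$row,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = "active TEs", fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
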