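# ggplot2 views of the main result types.

#' Plot a t-SNE embedding
#'
#' @param object An `rp_embedding`.
#' @param clusters Optional `rp_clusters` (or any tibble with `sample` and
#'   `cluster`) used to color the points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_embedding
#' @export
autoplot.rp_embedding <- function(object, clusters = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(clusters)) {
    df <- left_join(df, as_tibble(clusters)[c("sample", "cluster")], by = "sample")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p +
    ggplot2::geom_point(alpha = 0.8, size = 1.5) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' Plot a majority-rule SOM node coloring
#'
#' Hexagonal node layout with nodes colored by their majority cluster;
#' `"mixed"` and `"empty"` nodes are drawn in grey.
#'
#' @param object An `rp_som_coloring`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_som_coloring
#' @export
autoplot.rp_som_coloring <- function(object, ...) {
  df <- as_tibble(object)
  df$color <- factor(df$color)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$color)) +
    ggplot2::geom_point(shape = 21, size = 7, colour = "grey30") +
    ggplot2::scale_fill_manual(
      values = som_palette(levels(df$color)), name = "node color"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

som_palette <- function(levels) {
  clusters <- setdiff(levels, c("mixed", "empty"))
  pal <- setNames(
    grDevices::hcl.colors(max(3, length(clusters)), "Dark 3")[seq_along(clusters)],
    clusters
  )
  c(pal, mixed = "grey70", empty = "white")
}

#' Plot a Kaplan-Meier curve
#'
#' @param object An `rp_km`.
#' @param ... Unused.
#' @return A ggplot of the step survival estimate.
#' @method autoplot rp_km
#' @export
autoplot.rp_km <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, estimate = 1), object$curve[c("time", "estimate")])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (years)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-group log2 fold-change profiles
#'
#' @param profile The tibble from [log2_fc_profile()] (or an
#'   `rp_differential`).
#' @return A ggplot tile map, RPs on the x axis, groups on the y axis.
#' @export
plot_fc_profile <- function(profile) {
  df <- as_tibble(profile)
  df$rp <- factor(df$rp, levels = unique(df$rp))
  ggplot2::ggplot(df, ggplot2::aes(.data$rp, .data$group, fill = .data$log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}
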