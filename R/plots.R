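#' Plot size-bin histograms
#'
#' Bar chart of a [bin_histograms()] table; `what` selects the normalised
#' quantity on the y axis.
#'
#' @param object an `islet_bins` tibble.
#' @param what one of `"volume_fraction"`, `"volume_density"`,
#'   `"count_fraction"`, `"count_per_mm3"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.islet_bins <- function(object, what = c("volume_fraction", "volume_density",
                                                 "count_fraction", "count_per_mm3"),
                                ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  df$bin <- factor(sprintf("%.3g", df$bin_lo_um3 / 1e3),
                   levels = sprintf("%.3g", df$bin_lo_um3 / 1e3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data[[what]])) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = expression("size bin lower edge (" * 10^3 ~ mu * m^3 * ")"),
                  y = gsub("_", " ", what)) +
    ggplot2::theme_minimal()
}

#' Plot k-NN distance summaries
#'
#' Mean distance to the k nearest neighbours by islet size category and
#' target category.
#'
#' @param object an `islet_knn` tibble from [knn_distances()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.islet_knn <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$mean_knn_um))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to_category, y = .data$mean_knn_um,
                                   fill = .data$from_category)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "target category", y = "mean k-NN distance (µm)",
                  fill = "from") +
    ggplot2::theme_minimal()
}

#' Plot a composition spectrum
#'
#' Count and volume fractions per glucagon-fraction bin and per size bin.
#'
#' @param object a `composition_spectrum` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.composition_spectrum <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("count_fraction", "volume_fraction"),
                            names_to = "measure", values_to = "fraction")
  df$bin <- factor(df$bin, levels = unique(df$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$bin_type, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Maximum intensity projection of a channel
#'
#' @param grid a [voxel_grid()].
#' @param channel channel name.
#' @param axis projection axis: `"z"`, `"y"` or `"x"`.
#' @return a ggplot object.
#' @export
plot_mip <- function(grid, channel = "INS", axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  a <- get_channel(grid, channel)
  m <- switch(axis,
              z = apply(a, c(2, 3), max),
              y = apply(a, c(1, 3), max),
              x = apply(a, c(1, 2), max))
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s maximum intensity projection (%s)", channel, axis),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}
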