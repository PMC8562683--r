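#' Plot detected spots over an image
#'
#' @param image intensity matrix.
#' @param spots spot tibble (0-based coordinates).
#' @return A ggplot object.
#' @export
plot_spots <- function(image, spots) {
  df <- tibble::tibble(
    row = rep(0:(nrow(image) - 1), times = ncol(image)),
    col = rep(0:(ncol(image) - 1), each = nrow(image)),
    intensity = as.vector(image)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = spots, shape = 1, colour = "red", size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "counts")
}

#' Plot a registration correlation map
#'
#' Heatmap of the Pearson correlation at every candidate RDM-to-COM offset,
#' with the selected offset marked.
#'
#' @param reg an `m6a_registration`.
#' @return A ggplot object.
#' @export
plot_registration_map <- function(reg) {
  df <- tidy(reg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dcol, y = .data$drow,
                                   fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = df[df$is_best, ], colour = "red", shape = 4,
                        size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "column offset (wells)", y = "row offset (wells)",
                  fill = "r",
                  title = sprintf("registration: r = %.3f, z = %.1f",
                                  reg$correlation, reg$zscore))
}

#' Plot single-cell m6A levels by phenotype
#'
#' @param linked linked-cell tibble from [link_single_cells()].
#' @return A ggplot object.
#' @export
plot_m6a_levels <- function(linked) {
  ggplot2::ggplot(linked, ggplot2::aes(x = .data$phenotype,
                                       y = .data$m6a_level)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "m6A level (m6A+ / total molecules)")
}

#' Plot a t-SNE embedding of single cells
#'
#' @param embedding tibble from [embed_cells()].
#' @param colour_by column name used for point colour (e.g. "phenotype",
#'   "m6a_level").
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, colour_by = "phenotype") {
  ggplot2::ggplot(embedding,
                  ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = colour_by)
}
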