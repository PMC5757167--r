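# ggplot2 views of the main result objects.

#' Plot a contour raster
#'
#' Tile plot of a raster (or any image matrix), in image orientation
#' (row 1 at the top).
#'
#' @param raster A numeric matrix.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster) {
  df <- tidyr::expand_grid(row = seq_len(nrow(raster)),
                           col = seq_len(ncol(raster)))
  df$value <- as.numeric(raster)[(df$col - 1L) * nrow(raster) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @describeIn assign_groups Bar chart of similar-class sizes.
#' @param object A `similar_class_partition`.
#' @export
autoplot.similar_class_partition <- function(object, ...) {
  df <- object$assignment |>
    dplyr::count(.data$group) |>
    dplyr::mutate(group = factor(.data$group, levels = seq_len(object$m + 1L),
                                 labels = c(object$rep_names, "overflow")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n)) +
    ggplot2::geom_col(fill = "forestgreen") +
    ggplot2::labs(x = "similar class", y = "training images") +
    ggplot2::theme_minimal()
}

#' @describeIn classify_dwsrc Bar chart of per-species normalized errors.
#' @param object A `leaf_classification`.
#' @export
autoplot.leaf_classification <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$species, .data$error),
                                   y = .data$error, fill = .data$predicted)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "grey60"), guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "class reconstruction error") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_split Confusion-matrix heatmap.
#' @param object A `leaf_eval`.
#' @export
autoplot.leaf_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$Freq > 0, .data$Freq, "")),
                       color = "white", size = 3) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "darkgreen") +
    ggplot2::labs(x = "predicted", y = "truth", fill = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
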