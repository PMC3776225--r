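#' Plot an aggregated intensity histogram
#'
#' Cohort-average intensity distribution with quartile guides (solid median,
#' dashed 25th/75th percentiles), mirroring the standard presentation of
#' lesion intensity distributions.
#'
#' @param object an `aggregated_histogram`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot aggregated_histogram
#' @export
autoplot.aggregated_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = object$width, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$quartiles[2], linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = object$quartiles[c(1, 3)], linetype = 2) +
    ggplot2::labs(x = sprintf("standardized %s intensity", object$channel),
                  y = "probability density",
                  title = sprintf("%s intensity distribution (Bowley %.3f)",
                                  object$channel, object$bowley)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of per-structure burden across a cohort
#'
#' @param bt_list list of `burden_table`s.
#' @param metric `"n"` (count) or `"load_ppm"`.
#' @return A ggplot object.
#' @export
plot_burden <- function(bt_list, metric = c("load_ppm", "n")) {
  metric <- match.arg(metric)
  df <- dplyr::bind_rows(bt_list)
  df$structure <- factor(df$structure,
                         levels = c(as.character(LABEL_SET), "left", "right", "all"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$structure, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "structure (label code / aggregate)",
                  y = if (metric == "n") "hypointensity count" else "load (ppm of ICV)") +
    ggplot2::theme_minimal()
}

#' Axial slice of a spatial probability map
#'
#' @param map density [voxel_grid].
#' @param z axial slice index (default: slice of the map's maximum).
#' @return A ggplot object.
#' @export
plot_spatial_slice <- function(map, z = NULL) {
  stopifnot(is_voxel_grid(map))
  if (is.null(z)) z <- arrayInd(which.max(map$values), vg_shape(map))[3]
  sl <- map$values[, , z]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$p <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("spatial probability, axial slice %d", z),
                  fill = "density") +
    ggplot2::theme_minimal()
}
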