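#' Plot enhancement maps
#'
#' @param object an `enhancement_maps`.
#' @param which one of `"oft"`, `"intensity"`, `"orientation"`.
#' @param ... unused.
#' @return a ggplot raster of the selected map (rows increase downward).
#' @export
autoplot.enhancement_maps <- function(object, which = c("oft", "intensity",
                                                        "orientation"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  if (is.null(m)) stop("map `", which, "` has not been computed",
                       call. = FALSE)
  df <- tibble(row = as.vector(row(m)), col = as.vector(col(m)),
               value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    (if (which == "orientation") {
      ggplot2::scale_fill_gradientn(colours = c("#2166ac", "#f7f7f7",
                                                "#b2182b"),
                                    limits = c(-90, 90))
    } else {
      ggplot2::scale_fill_viridis_c()
    }) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", fill = which) +
    ggplot2::theme_minimal()
}

#' Plot reconstructed fiber traces
#'
#' @param object a `fiber_traces`.
#' @param ... unused.
#' @return a ggplot with one colored path per fiber.
#' @export
autoplot.fiber_traces <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   group = .data$fiber_id,
                                   colour = factor(.data$fiber_id))) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", colour = "fiber") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity scan as an error heatmap
#'
#' @param object a `sensitivity_scan`.
#' @param metric `"fp"`, `"fn"` or `"total"`.
#' @param ... unused.
#' @return a ggplot heatmap of the mean error over seeds, parameter value
#'   versus PSNR.
#' @export
autoplot.sensitivity_scan <- function(object, metric = c("total", "fp", "fn"),
                                      ...) {
  metric <- match.arg(metric)
  s <- tidy(object)
  col <- switch(metric, fp = "mean_fp", fn = "mean_fn", total = "mean_total")
  ggplot2::ggplot(s, ggplot2::aes(.data$value, .data$psnr,
                                  fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = attr(object, "vary"), y = "PSNR (dB)", fill = col) +
    ggplot2::theme_minimal()
}

#' Plot a width profile
#'
#' @param object a `width_profile`.
#' @param ... unused.
#' @return a ggplot of mean gradient versus distance level, with the edge
#'   level marked.
#' @export
autoplot.width_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$mean_gradient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "argmax_level"),
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = "distance level (px)", y = "mean gradient") +
    ggplot2::theme_minimal()
}
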