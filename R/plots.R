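# ggplot2 visualisations: relevance heatmaps (white-to-red), average-map
# panels, embedding scatter plots, and the CV bubble chart.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

red_scale <- function() {
  ggplot2::scale_fill_gradient(low = "white", high = "red3")
}

#' Heatmap of a relevance map
#'
#' White-to-red raster: the redder a pixel, the more positively it
#' contributed to the explained prediction.
#'
#' @param object a `relevance_map`.
#' @param ... unused.
#' @method autoplot relevance_map
#' @export
autoplot.relevance_map <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$relevance)) +
    ggplot2::geom_raster() +
    red_scale() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Relevance map, class %s", object$target_class),
      x = NULL, y = NULL, fill = "R"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of an average relevance map
#'
#' @param object an `average_map`.
#' @param ... unused.
#' @method autoplot average_map
#' @export
autoplot.average_map <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$relevance)) +
    ggplot2::geom_raster() +
    red_scale() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Average map, predicted age %s (n = %d)",
                      object$predicted_age, object$n_samples),
      x = NULL, y = NULL, fill = "R"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D embedding
#'
#' @param object an `embedding2d`.
#' @param labels optional point labels/groups used for colour.
#' @param ... unused.
#' @method autoplot embedding2d
#' @export
autoplot.embedding2d <- function(object, labels = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(labels)) d$label <- as.factor(labels)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.8) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") + ggplot2::theme_minimal()
}

#' Bubble chart of mean CV by age group
#'
#' Mean age-reading CV per group and data variant, circle radius
#' proportional to the stratum size.
#'
#' @param object a `cv_summary` from [mean_cv_by_group()].
#' @param ... unused.
#' @method autoplot cv_summary
#' @export
autoplot.cv_summary <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean_cv,
                                  colour = .data$variant,
                                  size = .data$n)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~split) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(x = NULL, y = "mean CV (%)", size = "n", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Render an otolith sample or relevance grid to an 8-bit grayscale PNG
#'
#' @param x an `otolith_sample`, `relevance_map`, `average_map` or matrix.
#' @param path output file.
#' @export
write_image_png <- function(x, path) {
  m <- if (inherits(x, "otolith_sample")) {
    x$image
  } else if (inherits(x, c("relevance_map", "average_map"))) {
    g <- if (inherits(x, "relevance_map")) x$scores else x$grid
    mx <- max(abs(g))
    if (mx > 0) g / mx else g
  } else {
    x
  }
  png::writePNG(clamp01(m), path)
}

#' Read a grayscale PNG as an image matrix
#'
#' @param path PNG file.
#' @return matrix of intensities in [0,1] (first channel if multi-channel).
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}
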