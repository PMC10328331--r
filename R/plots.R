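#' Heatmap of cohort z-scores
#'
#' Tile map of z-scores (treatment vs control, in control-SD units) per
#' group and metric, diverging palette centred at 0 so the direction of
#' each effect reads directly off the colour.
#'
#' @param object A `cep_zscore` from [cohort_zscores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cep_zscore <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$metric,
                               fill = .data$z)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey70") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z",
                  title = "Degeneration metrics vs control",
                  subtitle = paste0("z = (mean treatment - mean control) / SD control; control: ",
                                    attr(object, "control"))) +
    ggplot2::theme_minimal()
}

#' Overlay plot of an analyzed image
#'
#' The dendrite ROI with finalized tracks (one glyph per dendrite),
#' detected feature bounding boxes and break spans.
#'
#' @param object A `cep_analysis` from [analyze_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cep_analysis <- function(object, ...) {
  roi <- object$roi
  maxv <- 2^roi$bit_depth - 1
  df <- expand.grid(row = seq_len(nrow(roi$pixels)),
                    col = seq_len(ncol(roi$pixels)))
  df$value <- as.vector(roi$pixels) / maxv
  um <- roi$scale$microns_per_pixel
  tr <- dplyr::bind_rows(lapply(object$tracks, tidy))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col * um,
                                        y = .data$row * um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "green3",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um, distal at top)")
  if (nrow(tr)) {
    p <- p + ggplot2::geom_path(
      data = tr, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                              group = .data$dendrite,
                              color = factor(.data$dendrite)),
      linewidth = 0.3, alpha = 0.8) +
      ggplot2::labs(color = "dendrite")
  }
  ft <- object$features
  if (nrow(ft)) {
    half <- sqrt(ft$area_um2) / 2
    p <- p + ggplot2::geom_rect(
      data = ft,
      ggplot2::aes(xmin = .data$centroid_x_um - .data$max_caliper_um / 2,
                   xmax = .data$centroid_x_um + .data$max_caliper_um / 2,
                   ymin = .data$centroid_y_um - .data$max_caliper_um / 2,
                   ymax = .data$centroid_y_um + .data$max_caliper_um / 2),
      inherit.aes = FALSE, fill = NA, color = "white", linewidth = 0.3)
  }
  p
}

#' Distribution of categorical scores per group
#'
#' @param reports Report tibble with a `group` column (or a single run's
#'   reports; then one bar set is drawn).
#' @return A ggplot.
#' @export
plot_score_distribution <- function(reports) {
  df <- tibble::as_tibble(reports)
  if (!"group" %in% names(df)) df$group <- "all"
  df$categorical_score <- factor(df$categorical_score, levels = 0:4)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$categorical_score,
                                   fill = .data$group)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "categorical degeneration score", y = "dendrites",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
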