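#' Plot a synthetic slide with its lesions outlined
#'
#' Renders a (downsampled) view of the slide with ground-truth lesion pixels
#' tinted.
#'
#' @param object A `synthetic_slide`.
#' @param max_side Downsample so the longer side is at most this many pixels.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.synthetic_slide <- function(object, max_side = 512, ...) {
  f <- max(1, ceiling(max(dim(object$gt_mask)) / max_side))
  img <- block_mean_image(object$image, f)
  m <- block_mean(matrix(as.numeric(object$gt_mask), nrow(object$gt_mask)), f)
  sel <- m > 0
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- 0.5 * plane[sel] + 0.5 * c(1, 1, 0)[ch]
    img[, , ch] <- plane
  }
  ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(img), xmin = 0,
                               xmax = ncol(m), ymin = 0, ymax = nrow(m)) +
    ggplot2::coord_fixed(xlim = c(0, ncol(m)), ylim = c(0, nrow(m)),
                         expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d lesion(s), %.3f%% lesion pixels",
                                  object$spec$n_lesions,
                                  100 * mean(object$gt_mask))) +
    ggplot2::theme_void()
}

#' Plot the per-level work profile of a cascade run
#'
#' Bars compare the tiles each level would hold against the tiles the cascade
#' actually processed — the efficiency story of attention-gated selection.
#'
#' @param object A `cascade_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cascade_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$selection,
                           c("tiles_total", "tiles_processed"),
                           names_to = "what", values_to = "tiles")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$level), .data$tiles,
                                  fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(tiles_total = "grey70", tiles_processed = "#2166ac"),
      labels = c(tiles_total = "in grid", tiles_processed = "processed"),
      name = NULL) +
    ggplot2::labs(x = "pyramid level (1 = coarsest)", y = "tiles") +
    ggplot2::theme_minimal()
}

#' Plot LSD pairwise comparisons
#'
#' Mean differences with their confidence intervals, one row per method pair.
#'
#' @param object An `lsd_test` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lsd_test <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
                     pair = paste(.data$method_i, "-", .data$method_j))
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_difference, .data$pair)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "mean difference (I - J)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of per-slide metric distributions by method
#'
#' @param per_slide Tibble with a `method` column and metric columns.
#' @param metrics Metric columns to include.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(per_slide,
                                      metrics = c("precision", "recall",
                                                  "f_measure", "jaccard")) {
  d <- tidyr::pivot_longer(per_slide, dplyr::any_of(metrics),
                           names_to = "metric", values_to = "value")
  d <- d[!is.nan(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$method, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
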