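#' Plot an ROI intensity histogram
#'
#' Bar plot of voxel counts per intensity bin, the standard visualization of
#' within-ROI heterogeneity (a wider or multi-modal histogram = a more
#' heterogeneous tumor).
#'
#' @param object A [roi_histogram()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roi_histogram
#' @export
autoplot.roi_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.92,
                      fill = "grey30") +
    ggplot2::labs(
      x = sprintf("Voxel intensity (%s)", attr(object, "units")),
      y = "Voxel count",
      title = sprintf("Intensity histogram (%s)", attr(object, "roi"))) +
    ggplot2::theme_minimal()
}

#' Plot a CV group comparison
#'
#' Dot plot of per-tumor CV values by group with group-mean crossbars —
#' the conventional display for comparing heterogeneity between
#' marker-positive and marker-negative tumors.
#'
#' @param object A [compare_cv_groups()] result.
#' @param labels Length-2 group labels (group a, group b).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_group_test
#' @export
autoplot.cv_group_test <- function(object, labels = c("positive",
                                                      "negative"), ...) {
  df <- tibble(
    group = factor(rep(labels, c(object$n_a, object$n_b)), levels = labels),
    cv = c(object$cvs_a, object$cvs_b))
  means <- tibble(group = factor(labels, levels = labels),
                  cv = c(object$mean_a, object$mean_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$cv)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(ymin = .data$cv, ymax = .data$cv),
                           width = 0.4, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "Coefficient of variation",
                  subtitle = sprintf("%s: p = %.3g", object$method,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume with optional ROI outlines
#'
#' Grayscale raster of one z-slice with mask boundaries overlaid — a quick
#' visual check of delineation and contraction.
#'
#' @param volume An `image_volume`.
#' @param masks Optional named list of `roi_mask`s to outline.
#' @param z Slice index (1-based); defaults to the middle slice.
#' @return A ggplot object.
#' @export
plot_volume_slice <- function(volume, masks = list(), z = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  dm <- dim(volume$values)
  z <- z %||% ((dm[3] + 1) %/% 2)
  sl <- volume$values[, , z]
  df <- tibble(
    x = rep(seq_len(dm[1]), dm[2]),
    y = rep(seq_len(dm[2]), each = dm[1]),
    intensity = as.vector(sl))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(ratio = volume$spacing_mm[2] /
                           volume$spacing_mm[1]) +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)", fill = volume$units,
                  title = sprintf("Slice z = %d", z)) +
    ggplot2::theme_minimal()
  nms <- names(masks) %||% paste0("ROI ", seq_along(masks))
  for (i in seq_along(masks)) {
    msl <- masks[[i]]$values[, , z]
    if (!any(msl)) next
    mdf <- tibble(x = rep(seq_len(dm[1]), dm[2]),
                  y = rep(seq_len(dm[2]), each = dm[1]),
                  m = as.vector(msl), roi = nms[i])
    p <- p + ggplot2::geom_contour(
      data = mdf,
      ggplot2::aes(z = as.numeric(.data$m), colour = .data$roi),
      breaks = 0.5, inherit.aes = FALSE, linewidth = 0.6)
  }
  if (length(masks)) p <- p + ggplot2::labs(colour = "ROI")
  p
}
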