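# ggplot2 front-ends for the package's result types. These are diagnostic
# plots, not figure factories: raster views of images and kymographs,
# profile and recovery curves with dispersion ribbons, and a per-segment
# summary of the contact statistic against its flipped null.

#' @exportS3Method ggplot2::autoplot
autoplot.pixel_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_nm / 1000,
                                   y = .data$y_nm / 1000,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("channel \"%s\"", attr(object, "channel"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sholl_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius_um,
                                       y = .data$intersections)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius (µm)", y = "intersections",
                  subtitle = sprintf("total intersections: %d",
                                     attr(object, "total"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.normalized_frap_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$percent)) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (% of pre-bleach)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.frap_mean_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$mean_percent)) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = "dotted") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_percent - .data$sem_percent,
      ymax = .data$mean_percent + .data$sem_percent), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "average recovery (%)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.kymograph <- function(object, ...) {
  px_um <- attr(object, "pixel_size_nm") / 1000
  df <- tibble(
    position_um = rep((seq_len(nrow(object)) - 1) * px_um, ncol(object)),
    frame = rep(seq_len(ncol(object)) - 1L, each = nrow(object)),
    intensity = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$position_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "frame", y = "position along path (µm)") +
    ggplot2::theme_minimal()
}

#' Summary plot of per-segment contact fractions
#'
#' Paired view of the mask, enlarged-mask and flipped-null fractions across
#' segments, as analyzed by [analyze_segments()].
#'
#' @param results Tibble of per-segment contact results.
#' @return A ggplot object.
#' @export
plot_contact_summary <- function(results) {
  long <- results |>
    tidyr::pivot_longer(c("fraction_in_mask", "fraction_in_enlarged",
                          "fraction_flipped"),
                        names_to = "measure", values_to = "fraction") |>
    dplyr::mutate(measure = factor(
      .data$measure,
      levels = c("fraction_in_mask", "fraction_in_enlarged",
                 "fraction_flipped"),
      labels = c("ER mask", "enlarged mask", "flipped null")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure,
                                     y = 100 * .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "signal in mask (%)") +
    ggplot2::theme_minimal()
}
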