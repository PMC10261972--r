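#' Mean +/- SD spectra per group
#'
#' Ribbon plot of group mean spectra with a +/- 1 SD band, one facet per
#' measurement time.
#'
#' @param lib A [spectral_library()].
#' @param by Grouping columns (default species x time).
#' @param colour Column mapped to colour (default `"species"`).
#' @return A ggplot.
#' @export
plot_spectra <- function(lib, by = c("species", "measurement_time"),
                         colour = "species") {
  stats <- group_mean_sd(lib, by = by)
  p <- ggplot2::ggplot(stats, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$mean,
    colour = .data[[colour]], fill = .data[[colour]],
    group = interaction(!!!rlang::syms(by)))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance factor") +
    ggplot2::theme_minimal()
  if ("measurement_time" %in% by) {
    p <- p + ggplot2::facet_wrap(~measurement_time)
  }
  p
}

#' Per-wavelength variance-explained curves
#'
#' @param curves Output of [variance_explained()] (rows from several calls
#'   can be bound together).
#' @return A ggplot of R^2 against wavelength, coloured by factor.
#' @export
plot_variance_curve <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$wavelength_nm, y = .data$r2, colour = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measurement_time) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = expression(R^2), colour = "Factor") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.significance_mask <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm,
                                   y = .data$p_value)) +
    ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start_nm, xmax = .data$end_nm,
                   ymin = 0, ymax = 1),
      inherit.aes = FALSE, fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::labs(
      x = "Wavelength (nm)", y = "p-value",
      title = sprintf("%s: %s vs %s", object$species,
                      object$times[1], object$times[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectra_pca <- function(object, x = 1, y = 2,
                                 colour = "species", ...) {
  expl <- 100 * object$explained_fraction
  ggplot2::ggplot(object$scores, ggplot2::aes(
    x = .data[[paste0("PC", x)]], y = .data[[paste0("PC", y)]],
    colour = .data[[colour]])) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", x, expl[x]),
      y = sprintf("PC%d (%.1f%%)", y, expl[y]),
      title = sprintf("PCA scores, %s", object$time)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ri_fit <- function(object, ...) {
  df <- tibble(moist_pct = object$moist_pct, ri = object$ri)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$moist_pct, y = .data$ri)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(
      x = "Moisture content (%)", y = "Ratio index",
      subtitle = sprintf("RI = %.4g Moist%% + %.4g   (R2 = %.3f)",
                         object$slope, object$intercept, object$r2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ri_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l2, y = .data$l1,
                                   fill = .data$r2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(
      x = expression(lambda[2] ~ "(nm)"), y = expression(lambda[1] ~ "(nm)"),
      fill = expression(R^2),
      title = sprintf("Ratio-index scan, %s", object$time)) +
    ggplot2::theme_minimal()
}

#' Dendrogram of a hierarchical clustering
#'
#' Base-graphics dendrogram with cluster rectangles; the tree structure is
#' in `clust$tree` for custom plotting.
#'
#' @param x A `spectra_hclust`.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.spectra_hclust <- function(x, ...) {
  plot(x$tree, labels = x$labels$record_id, cex = 0.5,
       main = sprintf("Ward clustering, %s (k = %d)", x$time, x$k),
       xlab = "", sub = "", ...)
  stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}
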