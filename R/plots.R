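# ggplot2 presentation layer. Each audit table has a plot_*() helper; the
# result objects also support autoplot().

#' @export
autoplot.density_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "error (kcal/(mol*A))", y = "density",
      title = attr(object, "label")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.geometry_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(
      x = "frame", y = paste0(attr(object, "name"), " (", attr(object, "units"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-series error densities
#'
#' @param densities The `densities` tibble of an [run_audit()] report
#'   (columns `model`, `series`, `grid`, `density`).
#' @return A ggplot object.
#' @export
plot_error_densities <- function(densities) {
  ggplot2::ggplot(
    dplyr::filter(densities, .data$series != "energy"),
    ggplot2::aes(x = .data$grid, y = .data$density, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(
      x = "force error (kcal/(mol*A))", y = "density",
      colour = "element"
    ) +
    ggplot2::theme_minimal()
}

#' Plot smoothed error timelines
#'
#' @param timelines The `timelines` tibble of an [run_audit()] report.
#' @return A ggplot object.
#' @export
plot_timeline <- function(timelines) {
  long <- tidyr::pivot_longer(
    timelines[, c("model", "frame", "force_mae_smooth", "energy_abs_smooth")],
    c("force_mae_smooth", "energy_abs_smooth"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value, colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "frame", y = "smoothed error") +
    ggplot2::theme_minimal()
}

#' Plot ascending cluster error profiles
#'
#' @param profiles The `profiles` tibble of an [run_audit()] report (columns
#'   `model`, `rank`, `cluster`, `size`, `value`).
#' @return A ggplot object.
#' @export
plot_cluster_profile <- function(profiles) {
  ggplot2::ggplot(
    profiles,
    ggplot2::aes(x = .data$rank, y = .data$value, fill = .data$model)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "cluster (ascending error)", y = "force MAE (kcal/(mol*A))"
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted-vs-true correlation scatter
#'
#' @param scatter A [correlation_scatter()] tibble.
#' @return A ggplot object with outliers highlighted.
#' @export
plot_scatter <- function(scatter) {
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey30", "TRUE" = "#d7301f")) +
    ggplot2::labs(x = "reference", y = "predicted") +
    ggplot2::theme_minimal()
}

#' Overlay gyradius and smoothed energy error along the trajectory
#'
#' @param gyradius A [radius_of_gyration()] series.
#' @param timelines Optional `timelines` tibble of an [run_audit()] report;
#'   its smoothed energy error is overlaid (rescaled) when given.
#' @return A ggplot object.
#' @export
plot_gyradius <- function(gyradius, timelines = NULL) {
  p <- ggplot2::ggplot(gyradius, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "frame", y = "radius of gyration (A)") +
    ggplot2::theme_minimal()
  if (!is.null(timelines) && nrow(timelines) > 0) {
    tl <- timelines[timelines$model == timelines$model[1], ]
    rng <- range(gyradius$value)
    erng <- range(tl$energy_abs_smooth)
    if (diff(erng) > 0) {
      scaled <- rng[1] + (tl$energy_abs_smooth - erng[1]) / diff(erng) * diff(rng)
      p <- p + ggplot2::geom_line(
        data = tibble(frame = tl$frame, value = scaled),
        colour = "#e6550d", alpha = 0.8
      )
    }
  }
  p
}

#' @export
autoplot.audit_report <- function(object, type = c(
                                    "densities", "timeline",
                                    "clusters", "gyradius"
                                  ), ...) {
  type <- match.arg(type)
  switch(type,
    densities = plot_error_densities(object$densities),
    timeline = plot_timeline(object$timelines),
    clusters = plot_cluster_profile(object$profiles),
    gyradius = plot_gyradius(object$gyradius, object$timelines)
  )
}
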