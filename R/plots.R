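# ggplot2 views of the pipeline's result types.

#' @method autoplot tumoroid_ts
#' @export
autoplot.tumoroid_ts <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  t_h = (.data$t - 1) * 1,
                  `killing fraction` = .data$killing_fraction,
                  `T-cells in tumoroid` = as.numeric(.data$tcell_count)),
    cols = c("killing fraction", "T-cells in tumoroid"),
    names_to = "readout", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_h, .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~readout, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (frames)", y = NULL,
                  title = "Tumoroid killing and T-cell recruitment") +
    ggplot2::theme_minimal()
}

#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag_h, .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time lag (h)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tau <- seq(min(object$lag_h), max(object$lag_h), length.out = 100)
    pred <- tibble(lag_h = tau,
                   msd_um2 = 4 * fit$D_um2_h * tau + fit$v_um_h^2 * tau^2)
    p <- p + ggplot2::geom_line(data = pred, colour = "firebrick")
  }
  p
}

#' Plot T-cell trajectories in the lateral plane
#'
#' @param trajectories trajectory tibble (`cell_id, t_h, x_um, y_um, z_um`).
#' @param colour_by `"cell"` or `"time"`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, colour_by = c("cell", "time")) {
  colour_by <- match.arg(colour_by)
  aes <- if (colour_by == "cell") {
    ggplot2::aes(.data$x_um, .data$y_um, group = .data$cell_id,
                 colour = factor(.data$cell_id))
  } else {
    ggplot2::aes(.data$x_um, .data$y_um, group = .data$cell_id,
                 colour = .data$t_h)
  }
  ggplot2::ggplot(trajectories, aes) +
    ggplot2::geom_path(alpha = 0.7, show.legend = colour_by == "time") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = "T-cell trajectories (lateral projection)") +
    ggplot2::theme_minimal()
}
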