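#' Plot a trajectory log
#'
#' Path in the world frame, coloured by time.
#'
#' @param object a `trajectory_log` (from [run_locomotion()]) or any tibble
#'   with `x`, `y` and `tick`/`cycle` columns.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trajectory_log <- function(object, ...) {
  tvar <- if ("tick" %in% names(object)) "tick" else "cycle"
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       colour = .data[[tvar]])) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (model units)", y = "y (model units)",
                  colour = tvar) +
    ggplot2::theme_minimal()
}

#' Plot a scenario result
#'
#' The agent's per-cycle trajectory with start (circle) and end (cross)
#' marked.
#'
#' @param object a `scenario_result` from [run_scenario()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scenario_result <- function(object, ...) {
  log <- object$log
  tvar <- if ("cycle" %in% names(log)) "cycle" else "decision"
  ggplot2::ggplot(log, ggplot2::aes(.data$x, .data$y,
                                    colour = .data[[tvar]])) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = log$x[1], y = log$y[1], shape = 1,
                      size = 3) +
    ggplot2::annotate("point", x = log$x[nrow(log)], y = log$y[nrow(log)],
                      shape = 4, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$config$scenario,
                  x = "x (model units)", y = "y (model units)") +
    ggplot2::theme_minimal()
}

image_raster_df <- function(img) {
  data.frame(col = as.vector(col(img)), row = as.vector(row(img)),
             intensity = as.vector(unclass(img)))
}

#' Plot a rendered sensor image
#'
#' @param object a `panoramic_image` or `eye_image`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.panoramic_image <- function(object, ...) {
  ggplot2::ggplot(image_raster_df(object),
                  ggplot2::aes(.data$col, .data$row,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth column", y = "elevation row") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.panoramic_image
#' @export
autoplot.eye_image <- autoplot.panoramic_image

#' Plot a trail map
#'
#' @param object a [trail_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trail_map <- function(object, ...) {
  r <- object$raster
  df <- data.frame(
    x = object$origin[1] + (as.vector(col(r)) - 1) * object$res,
    y = object$origin[2] + (as.vector(row(r)) - 1) * object$res,
    intensity = as.vector(r))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey20", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a gait joint-angle series
#'
#' Line plot of the three active joint angles over time, faceted by leg.
#'
#' @param series a tibble from [gait_angle_series()].
#' @return a ggplot object.
#' @export
plot_gait_series <- function(series) {
  long <- tidyr_pivot(series)
  ggplot2::ggplot(long, ggplot2::aes(.data$tick, .data$angle,
                                     colour = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~leg) +
    ggplot2::labs(y = "angle (deg)") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(series) {
  dplyr::bind_rows(lapply(c("alpha", "beta", "gamma"), function(j) {
    tibble::tibble(tick = series$tick, leg = series$leg, joint = j,
                   angle = series[[j]])
  }))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a scenario result
#'
#' @param x a `scenario_result`.
#' @param ... unused.
#' @return the per-cycle trajectory log as a tibble.
#' @export
tidy.scenario_result <- function(x, ...) x$log

#' @export
tidy <- function(x, ...) UseMethod("tidy")
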