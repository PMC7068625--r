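# ggplot2 views of an orbit_analysis; quantitative output always goes
# through the CSV tables, plots are diagnostics.

state_scale <- function() {
  ggplot2::scale_colour_manual(
    values = c(transport = "#1b9e77", stationary = "#d95f02"),
    na.value = "grey70", name = NULL)
}

#' Plot the trajectory colored by motion state
#'
#' @param x An `orbit_analysis` object.
#' @return A ggplot.
#' @export
plot_track <- function(x) {
  stopifnot(inherits(x, "orbit_analysis"))
  df <- dplyr::left_join(
    dplyr::mutate(x$trajectory, point_index = dplyr::row_number()),
    point_states(x)[, c("point_index", "state")], by = "point_index")
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, colour = .data$state)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_equal() +
    state_scale() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Trajectory by motion state") +
    ggplot2::theme_minimal()
}

#' Plot the correlation amplitude and threshold
#'
#' Amplitude trace with the permutation threshold `T = M + w * sigma`;
#' windows above threshold are the transport calls.
#'
#' @param x An `orbit_analysis` object.
#' @return A ggplot.
#' @export
plot_amplitude <- function(x) {
  stopifnot(inherits(x, "orbit_analysis"))
  ggplot2::ggplot(x$amplitude, ggplot2::aes(.data$t_ms / 1000, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::geom_point(data = dplyr::filter(x$amplitude, .data$transport),
                        colour = "#1b9e77", size = 0.4) +
    ggplot2::geom_hline(yintercept = x$threshold$threshold,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "correlation amplitude A(t)",
                  title = sprintf("Amplitude vs threshold (w = %g)", x$params$w)) +
    ggplot2::theme_minimal()
}

#' Plot the correlation carpet
#'
#' Heat map of the windowed angle correlation over window start and lag.
#'
#' @param x An `orbit_analysis` object or a matrix from
#'   [correlation_carpet()].
#' @return A ggplot.
#' @export
plot_carpet <- function(x) {
  carpet <- if (inherits(x, "orbit_analysis")) x$carpet else x
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(carpet, .name_repair = "minimal"),
                  t = dplyr::row_number()),
    -"t", names_to = "tau", values_to = "cor")
  df$tau <- as.integer(df$tau)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$tau, fill = .data$cor)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Cor(t, τ)") +
    ggplot2::labs(x = "window start t", y = "lag τ",
                  title = "Angle correlation carpet") +
    ggplot2::theme_minimal()
}

#' Autoplot an analysis
#'
#' @param object An `orbit_analysis` object.
#' @param which `"track"`, `"amplitude"` or `"carpet"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.orbit_analysis <- function(object,
                                    which = c("amplitude", "track", "carpet"),
                                    ...) {
  which <- match.arg(which)
  switch(which,
         amplitude = plot_amplitude(object),
         track = plot_track(object),
         carpet = plot_carpet(object))
}
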