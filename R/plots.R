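#' Spike raster plot
#'
#' @param object A `sim_result`.
#' @param max_neurons Plot at most this many neurons (lowest indices).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, max_neurons = 200, ...) {
  sp <- dplyr::filter(object$spikes, .data$neuron < max_neurons)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time_ms, y = .data$neuron)) +
    ggplot2::geom_point(size = 0.2, shape = ".") +
    ggplot2::labs(x = "time (ms)", y = "neuron index",
                  title = sprintf("spike raster (nu_ext = %g /s)",
                                  object$drive$nu_ext)) +
    ggplot2::theme_minimal()
}

#' Plot one activity frame (raw or Mexican-hat filtered)
#'
#' @param frames An `activity_frames` object.
#' @param frame Frame number (1-based).
#' @param kernel Optional [build_ricker()] kernel: if given, the filtered
#'   image is shown.
#' @return A ggplot object.
#' @export
plot_frame <- function(frames, frame = 1, kernel = NULL) {
  stopifnot(inherits(frames, "activity_frames"))
  m <- frames$frames[[frame]]
  if (!is.null(kernel)) m <- torus_convolve(m, kernel)
  df <- tidyr::expand_grid(x = 0:(nrow(m) - 1), y = 0:(ncol(m) - 1))
  df$value <- m[cbind(df$x + 1, df$y + 1)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (is.null(kernel)) "spikes" else "filtered") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y (grid)", y = "x (grid)",
                  title = sprintf("frame %d (%g ms windows)", frame, frames$window_ms)) +
    ggplot2::theme_minimal()
}

#' Plot the connection probability vs distance profile
#'
#' @param profile Output of [empirical_distance_profile()].
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(profile) {
  ggplot2::ggplot(dplyr::filter(profile, !.data$empty),
                  ggplot2::aes(x = .data$distance, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "torus distance (grid units)",
                  y = "connection probability") +
    ggplot2::theme_minimal()
}

#' Plot the eigenvalue spectrum of a stability report
#'
#' Shows the kernel transform and the perturbation growth rate per
#' wavenumber; the instability condition is `zeta(k) > 0` somewhere.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$spectrum, c("w_tilde", "zeta"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(w_tilde = "kernel transform W~(k)",
                            zeta = "growth rate zeta(k)"))) +
    ggplot2::labs(x = "wavenumber k (rad / grid unit)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bump centroid tracks on the grid
#'
#' @param object A `bump_tracks` tibble.
#' @param min_lifespan Only tracks at least this many frames long.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bump_tracks
#' @export
autoplot.bump_tracks <- function(object, min_lifespan = 1, ...) {
  paths <- dplyr::bind_rows(
    purrr::map2(object$path, object$track,
                function(p, id) dplyr::mutate(p, track = id)))
  keep <- object$track[object$lifespan >= min_lifespan]
  paths <- dplyr::filter(paths, .data$track %in% keep)
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$cy, y = .data$cx,
                                      group = .data$track,
                                      colour = factor(.data$track))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y (grid)", y = "x (grid)", title = "bump centroid tracks") +
    ggplot2::theme_minimal()
}

#' Plot a drive sweep summary
#'
#' Mean rate and mean bump count against the background drive, with points
#' coloured by the classified state.
#'
#' @param sweep A tibble from [run_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("mean_rate", "mean_count"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$nu_ext, y = .data$value,
                                     colour = .data$state)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "background drive nu_ext (spikes/s)", y = NULL) +
    ggplot2::theme_minimal()
}
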