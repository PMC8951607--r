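#' Scree plot of tilt-PCA variance fractions
#'
#' @param object a `tilt_pca`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tilt_pca
#' @export
autoplot.tilt_pca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "principal component", y = "variance fraction (%)",
                  title = "Tilt-coherence PCA") +
    ggplot2::theme_minimal()
}

#' Displacement distribution with the fitted random-walk law
#'
#' @param object a `diffusion_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot diffusion_fit
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  r <- object$displacements$r
  grid <- seq(0, max(r) * 1.1, length.out = 200)[-1]
  curve <- tibble::tibble(r = grid,
                          p = random_walk_pdf(grid, max(object$D, 1e-12),
                                              object$window))
  ggplot2::ggplot(tibble::tibble(r = r), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p),
                       colour = "firebrick") +
    ggplot2::labs(x = "lateral displacement r (A)", y = "probability density",
                  title = sprintf("2D random-walk fit, window %g ps: D = %.3g A²/ps",
                                  object$window, object$D)) +
    ggplot2::theme_minimal()
}

#' Heat map of a 2D water density
#'
#' @param object a `density_map_2d`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot density_map_2d
#' @export
autoplot.density_map_2d <- function(object, ...) {
  lab <- if (attr(object, "plane") == "xy") c("x' (A)", "y' (A)") else c("x' (A)", "z' (A)")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$a, y = .data$b,
                                       fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[1], y = lab[2], fill = "probability",
                  title = "Confined-water positional probability") +
    ggplot2::theme_minimal()
}

#' Pore radius profile plot
#'
#' @param profile output of [radius_profile()].
#' @return a ggplot with the mean profile and a 1-sd ribbon.
#' @export
plot_radius_profile <- function(profile) {
  d <- profile[!is.na(profile$radius_mean), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$radius_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$radius_mean - .data$radius_sd,
                                      ymax = .data$radius_mean + .data$radius_sd),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "axial coordinate (A)", y = "inner radius (A)",
                  title = "Slice-based pore radius profile") +
    ggplot2::theme_minimal()
}

#' Per-residue out-of-plane (delta) angle plot
#'
#' @param deformation output of [radial_deformation()]; error bars are
#'   1.96 x the per-residue standard deviation.
#' @return a ggplot faceted by ring.
#' @export
plot_delta_angles <- function(deformation) {
  ggplot2::ggplot(deformation,
                  ggplot2::aes(x = factor(.data$residue), y = .data$delta_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$delta_mean - 1.96 * .data$delta_sd,
      ymax = .data$delta_mean + 1.96 * .data$delta_sd), width = 0.3) +
    ggplot2::facet_wrap(~ring, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "residue", y = "delta angle (deg)",
                  title = "Out-of-plane C-alpha angles") +
    ggplot2::theme_minimal()
}

#' Tilt-angle time series plot
#'
#' @param tilts output of [tilt_angles()].
#' @return a ggplot; the whole-tube tilt is drawn in black.
#' @export
plot_tilt_series <- function(tilts) {
  ggplot2::ggplot(tilts[tilts$unit != "tube", ],
                  ggplot2::aes(x = .data$time, y = .data$tilt,
                               colour = .data$unit)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_line(data = tilts[tilts$unit == "tube", ],
                       colour = "black", linewidth = 0.8) +
    ggplot2::labs(x = "time (ps)", y = "tilt (deg)", colour = "ring",
                  title = "Per-ring and whole-tube tilt") +
    ggplot2::theme_minimal()
}
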