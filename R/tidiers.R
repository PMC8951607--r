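#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tilt PCA
#'
#' @param x a `tilt_pca`.
#' @param ... unused.
#' @return tibble (component, eigenvalue, fraction, cumulative).
#' @method tidy tilt_pca
#' @export
tidy.tilt_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 fraction = x$fractions,
                 cumulative = cumsum(x$fractions))
}

#' @rdname tidy.tilt_pca
#' @method glance tilt_pca
#' @export
glance.tilt_pca <- function(x, ...) {
  tibble::tibble(n_rings = length(x$rings), n_frames = x$n_frames,
                 matrix = x$use, first_fraction = x$fractions[1])
}

#' Tidy a diffusion fit
#'
#' @param x a `diffusion_fit`.
#' @param ... unused.
#' @return tibble with one row per estimator (MLE and histogram
#'   least-squares).
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    term = c("D_mle", "D_hist"),
    estimate = c(x$D, x$D_hist),
    conf.low = c(x$conf_low, NA_real_),
    conf.high = c(x$conf_high, NA_real_))
}

#' @rdname tidy.diffusion_fit
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D = x$D, conf.low = x$conf_low, conf.high = x$conf_high,
                 window = x$window, n = x$n, n_eff = x$n_eff,
                 degenerate = x$degenerate)
}
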