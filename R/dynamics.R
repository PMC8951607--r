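#' Principal component analysis of per-ring tilt coherence
#'
#' Eigendecomposition of the Pearson correlation matrix (default) of the
#' per-ring tilt-angle time series. A dominant first component indicates
#' that the rings tilt as one body. Constant (zero-variance) series are
#' excluded with a warning. Variance fractions are invariant under
#' per-series affine rescaling because the correlation, not covariance,
#' matrix is used.
#'
#' @param tilts tibble as returned by [tilt_angles()] (frame, unit, tilt);
#'   the `"tube"` unit, if present, is ignored.
#' @param use `"correlation"` (default) or `"covariance"`.
#' @return object of class `tilt_pca`: eigenvalues, variance fractions
#'   (percent, descending), leading eigenvector, number of frames/rings.
#' @export
tilt_pca <- function(tilts, use = c("correlation", "covariance")) {
  use <- match.arg(use)
  tilts <- tilts[tilts$unit != "tube", ]
  wide <- tidyr::pivot_wider(tilts[, c("frame", "unit", "tilt")],
                             names_from = "unit", values_from = "tilt")
  m <- as.matrix(wide[, setdiff(names(wide), "frame")])
  if (nrow(m) < 10 * ncol(m))
    stop("tilt_pca needs at least 10 frames per ring series")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning("constant tilt series excluded: ring(s) ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than two non-constant tilt series")
  S <- if (use == "correlation") stats::cor(m) else stats::cov(m)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(
    eigenvalues = vals,
    fractions = 100 * vals / sum(vals),
    leading_vector = e$vectors[, 1],
    rings = colnames(m), n_frames = nrow(m), use = use),
    class = "tilt_pca")
}

#' @export
print.tilt_pca <- function(x, ...) {
  cat(sprintf("<tilt_pca> %d rings x %d frames (%s matrix)\n",
              length(x$rings), x$n_frames, x$use))
  cat("variance fractions (%):",
      paste(sprintf("%.1f", x$fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Centre-of-mass track of the peptide tube
#'
#' @param traj a `nanotube_trajectory`.
#' @param discard initial time (ps) to drop.
#' @return tibble (frame, time, x, y, z), mass-weighted over peptide atoms.
#' @export
com_series <- function(traj, discard = 0) {
  idx <- which(traj$time >= discard)
  sel <- which(traj$atoms$segment == "cp")
  w <- element_mass(traj$atoms$element[sel])
  w <- w / sum(w)
  com <- t(vapply(idx, function(t) {
    colSums(traj$coords[t, sel, , drop = TRUE] * w)
  }, numeric(3)))
  tibble::tibble(frame = idx, time = traj$time[idx],
                 x = com[, 1], y = com[, 2], z = com[, 3])
}

#' Lateral displacement magnitudes at a fixed time window
#'
#' Magnitudes of the in-plane (xy) displacement of the tube centre over
#' all start points of a sliding window. The default stride of a quarter
#' window gives overlapping, statistically dependent windows; the
#' effective sample size `n * stride / window` is carried along and used
#' by [fit_diffusion()]'s confidence interval.
#'
#' @param com tibble (time, x, y) as from [com_series()].
#' @param window window length, ps (at least 2 frames).
#' @param stride start-point spacing, ps; default `window / 4`.
#' @return object of class `displacement_set`: tibble (start, r) with
#'   window, dt, and effective-n attributes.
#' @export
lateral_displacements <- function(com, window, stride = NULL) {
  dt <- diff(com$time[1:2])
  if (!isTRUE(all.equal(diff(com$time), rep(dt, nrow(com) - 1))))
    stop("com series must be uniformly spaced in time")
  wf <- round(window / dt)
  if (wf < 1) stop("window must span at least one frame step")
  if (wf >= nrow(com)) stop("window longer than the trajectory")
  stride <- stride %||% (window / 4)
  sf <- max(1L, round(stride / dt))
  starts <- seq(1L, nrow(com) - wf, by = sf)
  r <- sqrt((com$x[starts + wf] - com$x[starts])^2 +
              (com$y[starts + wf] - com$y[starts])^2)
  out <- tibble::tibble(start = starts, r = r)
  structure(out, window = wf * dt, dt = dt,
            n_eff = min(length(r), length(r) * sf / wf),
            class = c("displacement_set", class(out)))
}

#' Probability density of the 2D random-walk displacement magnitude
#'
#' The displacement magnitude of an isotropic two-dimensional Brownian
#' walk with diffusion coefficient `D` observed over lag `t` follows the
#' Rayleigh-form law `p(r) = r / (2 D t) * exp(-r^2 / (4 D t))`, which
#' integrates to one, peaks at `sqrt(2 D t)`, and has mean
#' `sqrt(pi * D * t)`.
#'
#' @param r displacement magnitude(s), Angstrom.
#' @param D diffusion coefficient, Angstrom^2/ps.
#' @param t lag time, ps.
#' @return density values.
#' @export
random_walk_pdf <- function(r, D, t) {
  if (D <= 0 || t <= 0) stop("D and t must be positive")
  r / (2 * D * t) * exp(-r^2 / (4 * D * t))
}

#' Fit the lateral diffusion coefficient
#'
#' Primary estimator: the maximum-likelihood solution of the Rayleigh
#' model, `D = sum(r^2) / (4 t n)`, with a confidence interval from the
#' exact Gamma sampling distribution of `sum(r^2)` evaluated at the
#' effective sample size (windows overlapping by a factor k contribute
#' n/k independent observations). A histogram least-squares fit of
#' [random_walk_pdf()] is reported alongside as a cross-check.
#'
#' @param displacements a `displacement_set` from [lateral_displacements()].
#' @param level confidence level.
#' @param bins histogram bin count for the least-squares cross-check.
#' @return object of class `diffusion_fit`: `D` (MLE, A^2/ps), `conf_low`,
#'   `conf_high`, `D_hist`, `window`, `n`, `n_eff`, `degenerate` flag.
#' @export
fit_diffusion <- function(displacements, level = 0.95, bins = 30) {
  if (nrow(displacements) < 2) stop("need at least 2 displacement values")
  t <- attr(displacements, "window")
  r <- displacements$r
  n <- length(r)
  n_eff <- attr(displacements, "n_eff") %||% n
  S <- sum(r^2)
  D <- S / (4 * t * n)
  alpha <- (1 - level) / 2
  if (S == 0) {
    warning("all displacements are zero: degenerate fit")
    return(structure(list(D = 0, conf_low = 0, conf_high = 0, D_hist = 0,
                          window = t, n = n, n_eff = n_eff, level = level,
                          degenerate = TRUE, displacements = displacements),
                     class = "diffusion_fit"))
  }
  # S*(n_eff/n) ~ Gamma(shape n_eff, scale 4 D t)
  conf <- D * n_eff / stats::qgamma(c(1 - alpha, alpha), shape = n_eff)
  h <- graphics::hist(r, breaks = bins, plot = FALSE)
  sse <- function(Dx) sum((h$density - random_walk_pdf(h$mids, Dx, t))^2)
  D_hist <- stats::optimize(sse, interval = c(D / 20, D * 20))$minimum
  structure(list(D = D, conf_low = conf[1], conf_high = conf[2],
                 D_hist = D_hist, window = t, n = n, n_eff = n_eff,
                 level = level, degenerate = FALSE,
                 displacements = displacements),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> window %g ps, n = %d (n_eff = %.0f)\n",
              x$window, x$n, x$n_eff))
  cat(sprintf("  D (MLE)      = %.4g A^2/ps  [%.4g, %.4g] at %.0f%%\n",
              x$D, x$conf_low, x$conf_high, 100 * x$level))
  cat(sprintf("  D (hist fit) = %.4g A^2/ps\n", x$D_hist))
  invisible(x)
}

#' Block-average standard error of the mean
#'
#' Splits a (possibly autocorrelated) series into `n_blocks` contiguous
#' blocks and estimates the standard error of the overall mean from the
#' scatter of the block means; `ci95 = 1.96 * se` is exposed for
#' 95-percent error bars.
#'
#' @param x numeric series of length at least `2 * n_blocks`.
#' @param n_blocks number of contiguous blocks.
#' @return list (mean, se, ci95, n_blocks, block_means).
#' @export
block_error <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < 2 * n_blocks) stop("series too short for ", n_blocks, " blocks")
  size <- floor(n / n_blocks)
  use <- x[seq_len(size * n_blocks)]
  bm <- colMeans(matrix(use, nrow = size))
  se <- stats::sd(bm) / sqrt(n_blocks)
  list(mean = mean(use), se = se, ci95 = 1.96 * se, n_blocks = n_blocks,
       block_means = bm)
}
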