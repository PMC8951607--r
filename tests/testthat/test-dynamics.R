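make_tilt_tbl <- function(m) {
  tibble::tibble(frame = rep(seq_len(nrow(m)), ncol(m)),
                 time = rep(seq_len(nrow(m)), ncol(m)),
                 unit = rep(as.character(seq_len(ncol(m))), each = nrow(m)),
                 tilt = as.vector(m))
}

test_that("tilt PCA separates coherent from independent motion", {
  set.seed(41)
  common <- stats::filter(rnorm(10000), 0.99, method = "recursive")
  common <- as.numeric(common)
  # eight identical series: everything in the first component
  ident <- make_tilt_tbl(matrix(common, 10000, 8))
  expect_equal(tilt_pca(ident)$fractions[1], 100, tolerance = 1e-9)
  # independent white noise: fractions near 1/8 each
  noise <- make_tilt_tbl(matrix(rnorm(80000), 10000, 8))
  pn <- tilt_pca(noise)
  expect_lt(pn$fractions[1], 20)
  expect_true(all(abs(pn$fractions - 12.5) < 5))
  # coherent signal with noise-to-signal 0.2: first component > 90 %
  sig <- common / sd(common)
  coh <- make_tilt_tbl(outer(sig, rep(1, 8)) + 0.2 * matrix(rnorm(80000), ncol = 8))
  expect_gt(tilt_pca(coh)$fractions[1], 90)
})

test_that("tilt PCA uses the correlation matrix and flags degeneracies", {
  set.seed(43)
  m <- outer(rnorm(2000), rep(1, 4)) + 0.3 * matrix(rnorm(8000), ncol = 4)
  base <- tilt_pca(make_tilt_tbl(m))
  # per-series affine rescaling leaves fractions unchanged
  scaled <- sweep(sweep(m, 2, c(1, 10, 0.1, 5), "*"), 2, c(0, 3, -2, 7), "+")
  expect_equal(tilt_pca(make_tilt_tbl(scaled))$fractions, base$fractions,
               tolerance = 1e-9)
  expect_equal(sum(base$fractions), 100, tolerance = 1e-9)
  # constant series are dropped with a warning
  m2 <- cbind(m, 5)
  expect_warning(p2 <- tilt_pca(make_tilt_tbl(m2)), "constant")
  expect_equal(length(p2$eigenvalues), 4)
  # too-short series are rejected
  expect_error(tilt_pca(make_tilt_tbl(matrix(rnorm(80), 10, 8))), "10 frames")
})

test_that("displacement extraction handles degenerate motion exactly", {
  static <- tibble::tibble(frame = 1:100, time = 0:99,
                           x = 0, y = 0, z = 0)
  ds <- lateral_displacements(static, window = 10)
  expect_true(all(ds$r == 0))
  # pure drift: r = v * t exactly
  v <- 0.25
  drift <- tibble::tibble(frame = 1:100, time = 0:99,
                          x = v * (0:99), y = 0, z = 0)
  dd <- lateral_displacements(drift, window = 20, stride = 20)
  expect_equal(dd$r, rep(v * 20, nrow(dd)), tolerance = 1e-12)
  expect_error(lateral_displacements(drift, window = 200), "longer")
})

test_that("the 2D random-walk law integrates to one with the stated moments", {
  D <- 0.02; t <- 50
  expect_equal(stats::integrate(random_walk_pdf, 0, 20 * sqrt(D * t),
                                D = D, t = t)$value, 1, tolerance = 1e-6)
  # mode at sqrt(2 D t)
  grid <- seq(1e-3, 10, by = 1e-4)
  expect_equal(grid[which.max(random_walk_pdf(grid, D, t))], sqrt(2 * D * t),
               tolerance = 1e-3)
  # mean displacement sqrt(pi D t)
  m1 <- stats::integrate(function(r) r * random_walk_pdf(r, D, t), 0, Inf)$value
  expect_equal(m1, sqrt(pi * D * t), tolerance = 1e-6)
  expect_error(random_walk_pdf(1, -1, 10), "positive")
  expect_error(random_walk_pdf(1, 0.1, 0), "positive")
})

test_that("diffusion fitting recovers known inputs", {
  # closed form: all displacements equal r0
  ds <- structure(tibble::tibble(start = 1:200, r = 2),
                  window = 100, dt = 1, n_eff = 200,
                  class = c("displacement_set", "tbl_df", "tbl", "data.frame"))
  fit <- fit_diffusion(ds)
  expect_equal(fit$D, 4 / (4 * 100), tolerance = 1e-12)
  # all-zero displacements are degenerate
  ds0 <- structure(tibble::tibble(start = 1:200, r = 0),
                   window = 100, dt = 1, n_eff = 200,
                   class = class(ds))
  expect_warning(f0 <- fit_diffusion(ds0), "degenerate")
  expect_equal(f0$D, 0)
  # Brownian track: MLE within 5 % with 5000 windows, and the histogram
  # cross-check agrees with the MLE
  set.seed(47)
  D <- 0.01; dt <- 1
  n <- 500100
  com <- tibble::tibble(frame = seq_len(n), time = (seq_len(n) - 1) * dt,
                        x = cumsum(rnorm(n, sd = sqrt(2 * D * dt))),
                        y = cumsum(rnorm(n, sd = sqrt(2 * D * dt))),
                        z = 0)
  dsb <- lateral_displacements(com, window = 100, stride = 100)
  fitb <- fit_diffusion(dsb)
  expect_lt(abs(fitb$D / D - 1), 0.05)
  expect_lt(abs(fitb$D_hist / fitb$D - 1), 0.1)
  expect_true(fitb$conf_low < fitb$D && fitb$D < fitb$conf_high)
  # estimates from t and 2t windows agree within their intervals
  ds2 <- lateral_displacements(com, window = 200, stride = 200)
  fit2 <- fit_diffusion(ds2)
  expect_true(fit2$conf_low < fitb$D && fitb$D < fit2$conf_high)
})

test_that("the diffusion estimate ignores the xy frame orientation", {
  set.seed(53)
  n <- 20000
  com <- tibble::tibble(frame = 1:n, time = 0:(n - 1),
                        x = cumsum(rnorm(n, sd = 0.1)),
                        y = cumsum(rnorm(n, sd = 0.1)), z = 0)
  a <- fit_diffusion(lateral_displacements(com, window = 50))$D
  th <- 0.7
  rot <- com
  rot$x <- cos(th) * com$x - sin(th) * com$y
  rot$y <- sin(th) * com$x + cos(th) * com$y
  b <- fit_diffusion(lateral_displacements(rot, window = 50))$D
  expect_equal(b, a, tolerance = 1e-9)
})

test_that("block averaging reproduces the i.i.d. error and widens under correlation", {
  expect_equal(block_error(rep(3.2, 100))$se, 0)
  expect_error(block_error(1:5, n_blocks = 5), "too short")
  set.seed(59)
  sigma <- 2
  x <- rnorm(10000, sd = sigma)
  be <- block_error(x, n_blocks = 10)
  expect_lt(abs(be$se / (sigma / sqrt(10000)) - 1), 0.3)
  expect_equal(be$ci95, 1.96 * be$se)
  # positively autocorrelated series: block error exceeds the naive one
  ar <- as.numeric(stats::filter(rnorm(10000), 0.95, method = "recursive"))
  be_ar <- block_error(ar, n_blocks = 10)
  naive <- sd(ar) / sqrt(length(ar))
  expect_gt(be_ar$se, naive)
})
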