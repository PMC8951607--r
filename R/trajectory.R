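#' Nanotube trajectory container
#'
#' A `nanotube_trajectory` holds per-atom metadata once (a tibble, as in
#' [new_frame()]) plus a `n_frames x n_atoms x 3` coordinate array in
#' Angstrom, frame times in ps, an optional box, and — for synthetic
#' trajectories — the ground truth recorded by [simulate_trajectory()].
#'
#' @param atoms atom metadata tibble (coordinates ignored if present).
#' @param coords numeric array `c(n_frames, n_atoms, 3)`.
#' @param time numeric vector of frame times, ps.
#' @param box length-3 numeric or NULL.
#' @param ground_truth optional list, see [simulate_trajectory()].
#' @param spec optional [nanotube_spec()].
#' @return an object of class `nanotube_trajectory`.
#' @export
new_trajectory <- function(atoms, coords, time, box = NULL,
                           ground_truth = NULL, spec = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == nrow(atoms), dim(coords)[1] == length(time))
  meta <- tibble::as_tibble(atoms)
  meta$x <- NULL; meta$y <- NULL; meta$z <- NULL
  structure(list(atoms = meta, coords = coords, time = time, box = box,
                 ground_truth = ground_truth, spec = spec),
            class = "nanotube_trajectory")
}

#' @export
print.nanotube_trajectory <- function(x, ...) {
  cat(sprintf("<nanotube_trajectory> %d frames x %d atoms, t = %g..%g ps%s\n",
              n_frames(x), nrow(x$atoms), x$time[1], x$time[length(x$time)],
              if (!is.null(x$ground_truth)) " (with ground truth)" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `nanotube_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory
#'
#' @param traj a `nanotube_trajectory`.
#' @param i frame index (1-based).
#' @return a [new_frame()] tibble.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  atoms <- traj$atoms
  atoms$x <- traj$coords[i, , 1]
  atoms$y <- traj$coords[i, , 2]
  atoms$z <- traj$coords[i, , 3]
  new_frame(atoms, time = traj$time[i], box = traj$box, spec = traj$spec)
}

#' Long-format coordinates of a trajectory
#'
#' @param x a `nanotube_trajectory`.
#' @param ... unused.
#' @return a tibble (frame, time, atom_id, x, y, z).
#' @method as_tibble nanotube_trajectory
#' @export
as_tibble.nanotube_trajectory <- function(x, ...) {
  nf <- n_frames(x); na <- nrow(x$atoms)
  tibble::tibble(
    frame = rep(seq_len(nf), each = na),
    time = rep(x$time, each = na),
    atom_id = rep(x$atoms$atom_id, nf),
    x = as.vector(t(x$coords[, , 1, drop = TRUE])),
    y = as.vector(t(x$coords[, , 2, drop = TRUE])),
    z = as.vector(t(x$coords[, , 3, drop = TRUE])))
}

#' Simulate a rigid-body nanotube trajectory with known ground truth
#'
#' Imposes three independent motions on a static frame: (1) a whole-tube
#' tilt about the x axis whose angle follows an AR(1)-smoothed Gaussian
#' signal (coefficient 0.99, stationary sd = `tilt_common_amp`), plus
#' independent per-ring Gaussian tilt noise (`tilt_noise_sigma`) applied as
#' an extra rotation of each ring about its own centre — both rotations
#' share the x axis, so the true tilt of ring k at frame t is exactly
#' `common_t + noise_kt`; (2) a 2D Brownian walk of the tube centre in the
#' membrane (xy) plane with `<dx^2 + dy^2> = 4 * lateral_D * dt_frame` per
#' step, applied to peptide and water atoms (lipids stay put); (3) i.i.d.
#' Gaussian jitter on every atom coordinate. The RNG state is restored on
#' exit; a fixed seed gives a bit-reproducible trajectory.
#'
#' @param frame starting `nanotube_frame` (frame 0 geometry).
#' @param motion a [motion_spec()].
#' @return a `nanotube_trajectory` whose `ground_truth` element is a list
#'   with `nanotube` and `motion` specs, a `frames` tibble
#'   (frame, time, lat_x, lat_y, tilt_common) and a `ring_tilts` tibble
#'   (frame, ring, tilt_true; signed degrees).
#' @export
simulate_trajectory <- function(frame, motion = motion_spec()) {
  stopifnot(inherits(motion, "motion_spec"))
  spec <- frame_spec(frame)
  X0 <- frame_coords(frame)
  nf <- motion$n_frames
  na <- nrow(X0)
  mobile <- frame$segment %in% c("cp", "water")   # lipids are the static slab
  rings <- sort(unique(frame$ring[frame$segment == "cp" & !is.na(frame$ring)]))
  nr <- length(rings)
  ring_rows <- lapply(rings, function(k) which(frame$ring %in% k & frame$segment == "cp"))
  ring_ctr <- lapply(ring_rows, function(idx) colMeans(X0[idx, , drop = FALSE]))
  tube_ctr <- colMeans(X0[frame$segment == "cp", , drop = FALSE])

  withr::with_seed(motion$seed, {
    # common tilt: AR(1) with phi = 0.99, scaled to stationary sd = amp
    phi <- 0.99
    if (motion$tilt_common_amp > 0) {
      u <- numeric(nf)
      u[1] <- stats::rnorm(1)
      innov <- stats::rnorm(nf) * sqrt(1 - phi^2)
      for (t in 2:max(2, nf)) u[t] <- phi * u[t - 1] + innov[t]
      tilt_common <- motion$tilt_common_amp * u[seq_len(nf)]
    } else tilt_common <- numeric(nf)

    tilt_noise <- if (motion$tilt_noise_sigma > 0) {
      matrix(stats::rnorm(nf * nr, sd = motion$tilt_noise_sigma), nf, nr)
    } else matrix(0, nf, nr)

    if (motion$lateral_D > 0) {
      step_sd <- sqrt(2 * motion$lateral_D * motion$dt_frame)
      lat <- cbind(cumsum(stats::rnorm(nf, sd = step_sd)),
                   cumsum(stats::rnorm(nf, sd = step_sd)))
    } else lat <- matrix(0, nf, 2)

    coords <- array(NA_real_, c(nf, na, 3))
    any_tilt <- motion$tilt_common_amp > 0 || motion$tilt_noise_sigma > 0
    for (t in seq_len(nf)) {
      X <- X0
      if (any_tilt) {
        for (k in seq_len(nr)) {
          ang <- tilt_noise[t, k]
          if (ang != 0) {
            idx <- ring_rows[[k]]
            Rm <- rotation_matrix(c(1, 0, 0), ang)
            X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2, ring_ctr[[k]]) %*% t(Rm),
                              2, ring_ctr[[k]], "+")
          }
        }
        if (tilt_common[t] != 0) {
          Rm <- rotation_matrix(c(1, 0, 0), tilt_common[t])
          X[mobile, ] <- sweep(sweep(X[mobile, , drop = FALSE], 2, tube_ctr) %*% t(Rm),
                               2, tube_ctr, "+")
        }
      }
      X[mobile, 1] <- X[mobile, 1] + lat[t, 1]
      X[mobile, 2] <- X[mobile, 2] + lat[t, 2]
      coords[t, , ] <- X
    }
    if (motion$jitter_sigma > 0) {
      coords <- coords + stats::rnorm(length(coords), sd = motion$jitter_sigma)
    }
  })

  time <- (seq_len(nf) - 1) * motion$dt_frame
  gt <- list(
    nanotube = spec, motion = motion,
    frames = tibble::tibble(frame = seq_len(nf), time = time,
                            lat_x = lat[, 1], lat_y = lat[, 2],
                            tilt_common = tilt_common),
    ring_tilts = tibble::tibble(
      frame = rep(seq_len(nf), nr),
      ring = rep(rings, each = nf),
      tilt_true = as.vector(sweep(tilt_noise, 1, tilt_common, "+"))))
  new_trajectory(frame, coords, time, box = frame_box(frame),
                 ground_truth = gt, spec = spec)
}

#' Build a trajectory from a list of frames
#'
#' @param frames list of `nanotube_frame`s sharing the same atoms.
#' @return a `nanotube_trajectory`.
#' @export
trajectory_from_frames <- function(frames) {
  if (length(frames) == 0) stop("empty frame list")
  na <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), na, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frame_coords(frames[[i]])
  time <- vapply(seq_along(frames),
                 function(i) attr(frames[[i]], "time") %||% (i - 1), numeric(1))
  new_trajectory(frames[[1]], coords, time, box = frame_box(frames[[1]]),
                 spec = frame_spec(frames[[1]]))
}
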