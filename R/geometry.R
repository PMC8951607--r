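#' Geometric centre of a ring
#'
#' Unweighted centroid of the C-alpha positions of one ring.
#'
#' @param xyz n x 3 coordinate matrix (one ring's C-alphas, in residue order).
#' @return length-3 numeric.
#' @export
ring_center <- function(xyz) {
  if (nrow(xyz) < 3) stop("ring_center needs >= 3 points")
  colMeans(xyz)
}

#' Ring normal from alternating cross products
#'
#' The ring-plane normal is the normalized sum of the normalized cross
#' products of centre-relative position vectors two residues apart,
#' `r'_i x r'_(i+2)`, with cyclic indexing over all residues (for an
#' 8-residue ring, indices 7 and 8 wrap onto 1 and 2). This alternating
#' stencil makes the normal of an ideal D,L zigzag ring identical to that
#' of its flat counterpart: the +/- out-of-plane displacements cancel in
#' the symmetric sum. The sign is fixed to the +z hemisphere, or to
#' continuity with `prev` (previous frame's normal) when given.
#'
#' @param xyz n x 3 C-alpha coordinate matrix in residue order, n >= 5.
#' @param prev optional length-3 normal used for sign continuity.
#' @return unit length-3 numeric.
#' @export
ring_normal <- function(xyz, prev = NULL) {
  n <- nrow(xyz)
  if (n < 5) stop("ring_normal needs >= 5 residues")
  rc <- colMeans(xyz)
  rp <- sweep(xyz, 2, rc)
  a <- rp
  b <- rp[c(3:n, 1, 2), , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(cr^2))
  if (any(len < 1e-12))
    stop("collinear centre-relative vectors: ring normal undefined")
  nv <- colSums(cr / len)
  nv <- normalize(nv)
  ref <- if (is.null(prev)) c(0, 0, 1) else prev
  if (sum(nv * ref) < 0) nv <- -nv
  nv
}

#' Project centre-relative vectors onto the ring plane
#'
#' @param xyz n x 3 C-alpha coordinates of one ring.
#' @param center ring centre; computed if NULL.
#' @param normal unit ring normal; computed if NULL.
#' @return n x 3 matrix of in-plane vectors r'' (relative to the centre).
#' @export
project_to_plane <- function(xyz, center = NULL, normal = NULL) {
  center <- center %||% ring_center(xyz)
  normal <- normal %||% ring_normal(xyz)
  rp <- sweep(xyz, 2, center)
  rp - outer(drop(rp %*% normal), normal)
}

# Per-residue observables of one ring: |r''| (radial), delta (signed
# out-of-plane angle, degrees), theta (angle between r''_i and the sum of
# the other residues' in-plane unit vectors, degrees). The summands must
# be normalized: because the centre is the centroid, the raw in-plane
# vectors sum to zero exactly, making the complementary sum identically
# antiparallel to r''_i (always 180 degrees, no information); unit
# vectors break that cancellation so theta responds to angular distortion
# of the polygon.
ring_observables <- function(xyz, prev_normal = NULL) {
  rc <- ring_center(xyz)
  nv <- ring_normal(xyz, prev = prev_normal)
  rp <- sweep(xyz, 2, rc)
  comp <- drop(rp %*% nv)
  rpp <- rp - outer(comp, nv)
  radial <- sqrt(rowSums(rpp^2))
  delta <- rad2deg(asin(pmin(1, pmax(-1, comp / sqrt(rowSums(rp^2))))))
  rhat <- rpp / radial
  tot <- colSums(rhat)
  others <- sweep(-rhat, 2, tot, "+")    # sum over j != i of unit vectors
  if (any(sqrt(rowSums(others^2)) < 1e-12)) {
    warning("zero-length complementary sum vector: angular deviation undefined")
    theta <- rep(NA_real_, nrow(xyz))
  } else {
    theta <- vec_angle_rows(rpp, others)
  }
  list(center = rc, normal = nv, radial = radial, delta = delta, theta = theta)
}

#' Per-residue ring geometry of one frame
#'
#' Computes, for every ring, the centre, plane normal, and per-residue
#' decomposition: radial distance |r''| of the projected C-alpha from the
#' centre, signed out-of-plane angle delta between r' and the ring plane,
#' and the angular deviation theta between r''_i and the sum of the other
#' residues' in-plane unit vectors (180 degrees for a perfect polygon;
#' the summands are normalized because the raw complementary sum is
#' identically antiparallel to r''_i).
#'
#' @param frame a `nanotube_frame`.
#' @return tibble (ring, residue, radial, delta, theta) with the per-ring
#'   centres and normals in the `"rings"` attribute.
#' @export
ring_geometry <- function(frame) {
  coords <- ring_ca_coords(frame)
  obs <- lapply(coords, ring_observables)
  rings <- as.integer(names(coords))
  out <- purrr::map_dfr(seq_along(obs), function(i) {
    o <- obs[[i]]
    tibble::tibble(ring = rings[i], residue = seq_along(o$radial),
                   radial = o$radial, delta = o$delta, theta = o$theta)
  })
  attr(out, "rings") <- tibble::tibble(
    ring = rings,
    cx = vapply(obs, function(o) o$center[1], numeric(1)),
    cy = vapply(obs, function(o) o$center[2], numeric(1)),
    cz = vapply(obs, function(o) o$center[3], numeric(1)),
    nx = vapply(obs, function(o) o$normal[1], numeric(1)),
    ny = vapply(obs, function(o) o$normal[2], numeric(1)),
    nz = vapply(obs, function(o) o$normal[3], numeric(1)))
  out
}

#' Signed out-of-plane (delta) angles of one frame
#'
#' @param frame a `nanotube_frame`.
#' @return tibble (ring, residue, delta), degrees; sign alternates around a
#'   D,L zigzag ring.
#' @export
delta_angle <- function(frame) {
  ring_geometry(frame)[, c("ring", "residue", "delta")]
}

#' Angular deviation of each residue from the polygonal arrangement
#'
#' @param frame a `nanotube_frame`.
#' @return tibble (ring, residue, theta, theta_ideal); `theta` is the angle
#'   between r''_i and the sum of the remaining residues' in-plane unit
#'   vectors, `theta_ideal` its value (180 degrees) for an ideal polygon.
#' @export
angular_deviation <- function(frame) {
  out <- ring_geometry(frame)[, c("ring", "residue", "theta")]
  out$theta_ideal <- 180
  out
}

# Per-frame, per-ring geometry over a trajectory, with normal-sign
# continuity. Returns list(residues = tibble(frame, time, ring, residue,
# radial, delta, theta) or NULL when residues = FALSE, rings =
# tibble(frame, time, ring, cx..nz)). Accumulates into preallocated
# matrices: trajectories run to thousands of frames.
geometry_series <- function(traj, discard = 0, residues = TRUE) {
  idx <- which(traj$time >= discard)
  atoms <- traj$atoms
  ca_sel <- which(atoms$segment == "cp" & atoms$name == "CA" & !is.na(atoms$ring))
  ca <- atoms[ca_sel, ]
  ord <- order(ca$ring, ca$resid)
  ca_sel <- ca_sel[ord]
  ring_of <- atoms$ring[ca_sel]
  rings <- sort(unique(ring_of))
  nr <- length(rings)
  nres <- sum(ring_of == rings[1])
  ring_rows <- lapply(rings, function(k) which(ring_of == k))
  nf <- length(idx)
  prev <- vector("list", nr)
  ring_mat <- matrix(NA_real_, nf * nr, 6)      # cx cy cz nx ny nz
  res_mat <- if (residues) matrix(NA_real_, nf * nr * nres, 3) else NULL
  for (ii in seq_len(nf)) {
    t <- idx[ii]
    xyz_all <- traj$coords[t, ca_sel, , drop = TRUE]
    for (kk in seq_len(nr)) {
      xyz <- xyz_all[ring_rows[[kk]], , drop = FALSE]
      row <- (ii - 1) * nr + kk
      if (residues) {
        o <- ring_observables(xyz, prev_normal = prev[[kk]])
        prev[[kk]] <- o$normal
        ring_mat[row, ] <- c(o$center, o$normal)
        rr <- ((row - 1) * nres + 1):(row * nres)
        res_mat[rr, ] <- cbind(o$radial, o$delta, o$theta)
      } else {
        nv <- ring_normal(xyz, prev = prev[[kk]])
        prev[[kk]] <- nv
        ring_mat[row, ] <- c(colMeans(xyz), nv)
      }
    }
  }
  rings_tbl <- tibble::tibble(
    frame = rep(idx, each = nr), time = rep(traj$time[idx], each = nr),
    ring = rep(rings, nf),
    cx = ring_mat[, 1], cy = ring_mat[, 2], cz = ring_mat[, 3],
    nx = ring_mat[, 4], ny = ring_mat[, 5], nz = ring_mat[, 6])
  res_tbl <- if (residues) tibble::tibble(
    frame = rep(idx, each = nr * nres),
    time = rep(traj$time[idx], each = nr * nres),
    ring = rep(rep(rings, each = nres), nf),
    residue = rep(seq_len(nres), nf * nr),
    radial = res_mat[, 1], delta = res_mat[, 2], theta = res_mat[, 3]) else NULL
  list(residues = res_tbl, rings = rings_tbl)
}

#' Radial deformation statistics over a trajectory
#'
#' Time-mean and standard deviation of the in-plane radial distance of each
#' C-alpha from its ring centre.
#'
#' @param traj a `nanotube_trajectory`.
#' @param discard initial time (ps) to drop before averaging.
#' @return tibble (ring, residue, radial_mean, radial_sd, delta_mean,
#'   delta_sd, theta_mean, theta_sd).
#' @export
radial_deformation <- function(traj, discard = 0) {
  gs <- geometry_series(traj, discard = discard)$residues
  dplyr::summarise(
    dplyr::group_by(gs, .data$ring, .data$residue),
    radial_mean = mean(.data$radial), radial_sd = sd_or_zero(.data$radial),
    delta_mean = mean(.data$delta), delta_sd = sd_or_zero(.data$delta),
    theta_mean = mean(.data$theta), theta_sd = sd_or_zero(.data$theta),
    .groups = "drop")
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Centre-of-mass distance between rings over time
#'
#' Mass-weighted (standard atomic masses by element) centre-of-mass
#' distance between pairs of rings, per frame. By default all consecutive
#' pairs are reported.
#'
#' @param traj a `nanotube_trajectory`.
#' @param ring_a,ring_b specific ring indices, or NULL for all consecutive
#'   pairs.
#' @param discard initial time (ps) to drop.
#' @return tibble (frame, time, pair, distance), Angstrom.
#' @export
com_distance_series <- function(traj, ring_a = NULL, ring_b = NULL, discard = 0) {
  atoms <- traj$atoms
  idx <- which(traj$time >= discard)
  rings <- sort(unique(atoms$ring[atoms$segment == "cp" & !is.na(atoms$ring)]))
  pairs <- if (!is.null(ring_a) && !is.null(ring_b)) {
    list(c(ring_a, ring_b))
  } else {
    lapply(seq_len(length(rings) - 1), function(i) rings[i + 0:1])
  }
  sel <- lapply(rings, function(k) which(atoms$ring %in% k & atoms$segment == "cp"))
  names(sel) <- rings
  w <- lapply(sel, function(s) {
    m <- element_mass(atoms$element[s]); m / sum(m)
  })
  com <- function(t, k) {
    s <- sel[[as.character(k)]]
    colSums(traj$coords[t, s, , drop = TRUE] * w[[as.character(k)]])
  }
  purrr::map_dfr(pairs, function(p) {
    d <- vapply(idx, function(t) vnorm(com(t, p[1]) - com(t, p[2])), numeric(1))
    tibble::tibble(frame = idx, time = traj$time[idx],
                   pair = sprintf("%d-%d", p[1], p[2]), distance = d)
  })
}

#' Per-ring and whole-tube tilt angles
#'
#' Tilt of each ring is the angle between its plane normal and the membrane
#' normal, folded to \[0, 90\] degrees; the whole-tube tilt uses the mean of
#' the per-ring unit normals.
#'
#' @param traj a `nanotube_trajectory`.
#' @param membrane_normal reference direction, default +z.
#' @param discard initial time (ps) to drop.
#' @return tibble (frame, time, unit, tilt) where `unit` is the ring number
#'   as character or `"tube"`.
#' @export
tilt_angles <- function(traj, membrane_normal = c(0, 0, 1), discard = 0) {
  mn <- normalize(membrane_normal)
  rg <- geometry_series(traj, discard = discard, residues = FALSE)$rings
  nmat <- as.matrix(rg[, c("nx", "ny", "nz")])
  ct <- abs(drop(nmat %*% mn))
  per_ring <- tibble::tibble(frame = rg$frame, time = rg$time,
                             unit = as.character(rg$ring),
                             tilt = rad2deg(acos(pmin(1, ct))))
  # whole-tube tilt from the per-frame mean of the ring normals
  nr <- length(unique(rg$ring))
  fidx <- rep(seq_len(nrow(rg) / nr), each = nr)
  mean_n <- cbind(tapply(rg$nx, fidx, mean), tapply(rg$ny, fidx, mean),
                  tapply(rg$nz, fidx, mean))
  mean_n <- mean_n / sqrt(rowSums(mean_n^2))
  tube <- tibble::tibble(frame = rg$frame[!duplicated(fidx)],
                         time = rg$time[!duplicated(fidx)],
                         unit = "tube",
                         tilt = rad2deg(acos(pmin(1, abs(drop(mean_n %*% mn))))))
  dplyr::arrange(dplyr::bind_rows(per_ring, tube), .data$frame, .data$unit)
}
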