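#' Instantaneous channel axis
#'
#' Least-squares line through the ring centres, oriented along the mean
#' ring normal.
#'
#' @param frame a `nanotube_frame` with at least 2 rings.
#' @return list with `point` (centroid of ring centres) and `direction`
#'   (unit vector).
#' @export
channel_axis <- function(frame) {
  rg <- attr(ring_geometry(frame), "rings")
  if (nrow(rg) < 2) stop("channel axis needs >= 2 rings")
  ctr <- as.matrix(rg[, c("cx", "cy", "cz")])
  p <- unname(colMeans(ctr))
  d <- svd(sweep(ctr, 2, p))$v[, 1]
  mean_normal <- colMeans(as.matrix(rg[, c("nx", "ny", "nz")]))
  if (sum(d * mean_normal) < 0) d <- -d
  list(point = p, direction = unname(normalize(d)))
}

# Axial coordinate t and radial distance of points from an axis.
axis_coords <- function(xyz, axis) {
  rel <- sweep(xyz, 2, axis$point)
  t <- drop(rel %*% axis$direction)
  radial <- sqrt(pmax(0, rowSums(rel^2) - t^2))
  list(t = t, radial = radial)
}

# Axial positions of the ring planes (projections of ring centres on the
# axis) and the mean spacing.
ring_axial_positions <- function(frame, axis = NULL) {
  axis <- axis %||% channel_axis(frame)
  rg <- attr(ring_geometry(frame), "rings")
  ctr <- as.matrix(rg[, c("cx", "cy", "cz")])
  t <- sort(drop(sweep(ctr, 2, axis$point) %*% axis$direction))
  list(t = t, spacing = mean(diff(t)), axis = axis)
}

#' Channel-region criterion
#'
#' Waters count as "inside" when their oxygen lies within `radius_cut` of
#' the instantaneous tube axis and axially between the terminal ring
#' planes extended by `mouth_pad` times the ring spacing on each side.
#'
#' @param radius_cut cylinder radius, Angstrom.
#' @param mouth_pad axial extension beyond the terminal ring planes, in
#'   units of the inter-ring spacing.
#' @return list of class `channel_region`.
#' @export
channel_region <- function(radius_cut = 4.0, mouth_pad = 0.5) {
  if (radius_cut <= 0) stop("radius_cut must be > 0")
  structure(list(radius_cut = radius_cut, mouth_pad = mouth_pad),
            class = "channel_region")
}

#' Water molecules inside the channel
#'
#' @param frame a `nanotube_frame` containing water (resname `SOL`).
#' @param region a [channel_region()].
#' @param water_resname residue name(s) identifying water.
#' @return tibble (resid, atom_id, t, radial) of in-channel water oxygens.
#' @export
channel_waters <- function(frame, region = channel_region(),
                           water_resname = c("SOL", "HOH", "WAT")) {
  ow <- frame[frame$segment == "water" & frame$element == "O" &
                frame$resname %in% water_resname, ]
  if (nrow(ow) == 0)
    return(tibble::tibble(resid = integer(), atom_id = integer(),
                          t = numeric(), radial = numeric()))
  rap <- ring_axial_positions(frame)
  ac <- axis_coords(as.matrix(ow[, c("x", "y", "z")]), rap$axis)
  lo <- rap$t[1] - region$mouth_pad * rap$spacing
  hi <- rap$t[length(rap$t)] + region$mouth_pad * rap$spacing
  keep <- ac$radial <= region$radius_cut & ac$t >= lo & ac$t <= hi
  tibble::tibble(resid = ow$resid[keep], atom_id = ow$atom_id[keep],
                 t = ac$t[keep], radial = ac$radial[keep])
}

#' Number of waters inside the channel
#'
#' @inheritParams channel_waters
#' @return integer count.
#' @export
count_channel_waters <- function(frame, region = channel_region(),
                                 water_resname = c("SOL", "HOH", "WAT")) {
  nrow(channel_waters(frame, region, water_resname))
}

#' Axial occupancy pattern of the channel water
#'
#' Splits the channel into alternating slots — windows of half the ring
#' spacing centred on each ring plane and on each inter-ring midpoint —
#' and reports the time-mean water occupancy of each slot. The pattern is
#' labelled `(a-b)n` when every plane-slot mean rounds to `a` and every
#' gap-slot mean to `b`; anything else is `other`.
#'
#' @param traj a `nanotube_trajectory` (a single `nanotube_frame` is also
#'   accepted).
#' @param region a [channel_region()].
#' @param discard initial time (ps) to drop.
#' @return object of class `axial_pattern`: list with `slots` (tibble:
#'   slot, type, t, occupancy) and `label`.
#' @export
axial_pattern <- function(traj, region = channel_region(), discard = 0) {
  frames <- if (inherits(traj, "nanotube_frame")) list(traj) else {
    idx <- which(traj$time >= discard)
    lapply(idx, function(t) get_frame(traj, t))
  }
  per_frame <- lapply(frames, function(fr) {
    rap <- ring_axial_positions(fr)
    cw <- channel_waters(fr, region)
    planes <- rap$t
    gaps <- utils::head(rap$t, -1) + rap$spacing / 2
    half <- rap$spacing / 4
    occ_p <- vapply(planes, function(z) sum(abs(cw$t - z) <= half), numeric(1))
    occ_g <- vapply(gaps, function(z) sum(abs(cw$t - z) <= half), numeric(1))
    c(occ_p, occ_g)
  })
  fr1 <- frames[[1]]
  rap <- ring_axial_positions(fr1)
  n_p <- length(rap$t); n_g <- n_p - 1
  occ <- Reduce(`+`, per_frame) / length(per_frame)
  slots <- tibble::tibble(
    slot = seq_len(n_p + n_g),
    type = c(rep("plane", n_p), rep("gap", n_g)),
    t = c(rap$t, utils::head(rap$t, -1) + rap$spacing / 2),
    occupancy = occ)
  slots <- dplyr::arrange(slots, .data$t)
  a <- unique(round(occ[1:n_p])); b <- unique(round(occ[n_p + seq_len(n_g)]))
  label <- if (length(a) == 1 && length(b) == 1 && (a > 0 || b > 0)) {
    sprintf("(%d-%d)n", a, b)
  } else "other"
  structure(list(slots = slots, label = label), class = "axial_pattern")
}

#' @export
print.axial_pattern <- function(x, ...) {
  cat(sprintf("<axial_pattern> %s\n", x$label))
  print(as.data.frame(x$slots), row.names = FALSE)
  invisible(x)
}

#' 2D positional probability map of channel water
#'
#' Water-oxygen positions are expressed in the tube frame (axis = z', an
#' arbitrary fixed in-plane direction = x'), restricted to the axial span
#' of the `inner_rings` central rings and to `region$radius_cut` radially,
#' then histogrammed on a square grid and normalized to unit total
#' probability.
#'
#' @param traj a `nanotube_trajectory` or single frame.
#' @param plane `"xy"` (transversal) or `"xz"` (longitudinal).
#' @param region a [channel_region()].
#' @param bin bin width, Angstrom.
#' @param inner_rings number of central rings considered (default 6).
#' @param discard initial time (ps) to drop.
#' @return object of class `density_map_2d`: tibble (a, b, prob) of bin
#'   centres, with plane and bin attributes.
#' @export
density_map <- function(traj, plane = c("xy", "xz"), region = channel_region(),
                        bin = 0.5, inner_rings = 6, discard = 0) {
  plane <- match.arg(plane)
  frames <- if (inherits(traj, "nanotube_frame")) list(traj) else {
    idx <- which(traj$time >= discard)
    lapply(idx, function(t) get_frame(traj, t))
  }
  pts <- purrr::map_dfr(frames, function(fr) {
    rap <- ring_axial_positions(fr)
    n_p <- length(rap$t)
    drop_each <- max(0, (n_p - inner_rings) / 2)
    lo <- rap$t[1 + floor(drop_each)]
    hi <- rap$t[n_p - floor(drop_each)]
    ow <- fr[fr$segment == "water" & fr$element == "O", ]
    if (nrow(ow) == 0) return(tibble::tibble(u = numeric(), v = numeric(),
                                             w = numeric()))
    xyz <- as.matrix(ow[, c("x", "y", "z")])
    d <- rap$axis$direction
    ex <- normalize(c(1, 0, 0) - d[1] * d)
    ey <- c(d[2] * ex[3] - d[3] * ex[2], d[3] * ex[1] - d[1] * ex[3],
            d[1] * ex[2] - d[2] * ex[1])
    rel <- sweep(xyz, 2, rap$axis$point)
    u <- drop(rel %*% ex); v <- drop(rel %*% ey); w <- drop(rel %*% d)
    keep <- w >= lo & w <= hi & sqrt(u^2 + v^2) <= region$radius_cut
    tibble::tibble(u = u[keep], v = v[keep], w = w[keep])
  })
  ab <- switch(plane, xy = pts[, c("u", "v")], xz = pts[, c("u", "w")])
  names(ab) <- c("a", "b")
  if (nrow(ab) == 0) {
    warning("no waters in the mapped region: all-zero map")
    out <- tibble::tibble(a = numeric(), b = numeric(), prob = numeric())
  } else {
    brks <- function(x) {
      r <- range(x)
      seq(floor(r[1] / bin) * bin, ceiling(r[2] / bin) * bin + bin, by = bin)
    }
    ba <- brks(ab$a); bb <- brks(ab$b)
    h <- table(cut(ab$a, ba, include.lowest = TRUE),
               cut(ab$b, bb, include.lowest = TRUE))
    out <- tibble::as_tibble(expand.grid(
      a = utils::head(ba, -1) + bin / 2, b = utils::head(bb, -1) + bin / 2))
    out$prob <- as.vector(h) / sum(h)
  }
  structure(out, plane = plane, bin = bin,
            class = c("density_map_2d", class(out)))
}

#' Slice-based inner radius profile of the pore
#'
#' The channel is cut into `n_slices` axial slices between the channel
#' bounds. At each slice position the inner radius is the minimum, over
#' pore-lining (peptide) atoms whose van der Waals sphere (or, for small
#' radii, whose slice bin) reaches the slice, of the atom's distance to
#' the axis minus the in-slice chord of its sphere,
#' `radial - sqrt(r_vdw^2 - dz^2)`, floored at zero. Slices reached by no
#' atom are reported as NA. This is a deliberately simple estimator: it
#' reproduces the minima-at-ring-planes / maxima-between-planes pattern
#' but does not emulate spherical-probe pathway finders, so absolute
#' values are not comparable to those.
#'
#' @param traj a `nanotube_trajectory` or single frame.
#' @param n_slices number of axial slices.
#' @param region a [channel_region()] fixing the axial bounds.
#' @param use_vdw subtract van der Waals radii (default); if FALSE atoms
#'   are treated as points binned into slices.
#' @param discard initial time (ps) to drop.
#' @return tibble (slice, t, radius_mean, radius_sd, n_frames_defined).
#' @export
radius_profile <- function(traj, n_slices = 100, region = channel_region(),
                           use_vdw = TRUE, discard = 0) {
  frames <- if (inherits(traj, "nanotube_frame")) list(traj) else {
    idx <- which(traj$time >= discard)
    lapply(idx, function(t) get_frame(traj, t))
  }
  rap1 <- ring_axial_positions(frames[[1]])
  lo <- rap1$t[1] - region$mouth_pad * rap1$spacing
  hi <- rap1$t[length(rap1$t)] + region$mouth_pad * rap1$spacing
  edges <- seq(lo, hi, length.out = n_slices + 1)
  half <- diff(edges)[1] / 2
  mids <- utils::head(edges, -1) + half
  per_frame <- vapply(frames, function(fr) {
    axis <- channel_axis(fr)
    cp <- fr[fr$segment == "cp", ]
    ac <- axis_coords(as.matrix(cp[, c("x", "y", "z")]), axis)
    rv <- if (use_vdw) vdw_radius(cp$element) else rep(0, nrow(cp))
    # atoms x slices: axial offset of each atom from each slice position
    dz <- outer(ac$t, mids, "-")
    reach <- abs(dz) <= pmax(rv, half)
    chord <- sqrt(pmax(0, rv^2 - dz^2))
    dim(chord) <- dim(dz)
    contrib <- ac$radial - chord
    contrib[contrib < 0] <- 0
    contrib[!reach] <- NA_real_
    suppressWarnings(apply(contrib, 2, min, na.rm = TRUE))
  }, numeric(n_slices))
  per_frame <- matrix(per_frame, nrow = n_slices)
  per_frame[!is.finite(per_frame)] <- NA_real_
  tibble::tibble(
    slice = seq_len(n_slices), t = mids,
    radius_mean = apply(per_frame, 1, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }),
    radius_sd = apply(per_frame, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else stats::sd(v)
    }),
    n_frames_defined = apply(per_frame, 1, function(v) sum(!is.na(v))))
}

#' Local minima of a (possibly masked) radius profile
#'
#' Within each contiguous run of unmasked slices, consecutive slices of
#' equal radius (within `tol`) are merged into plateaus; a plateau is a
#' local minimum when it has neighbours on both sides within the run and
#' both are larger. Minima of prominence (height of the lower of the two
#' flanking maxima above the minimum) below `min_prominence` are
#' discarded: a hard-sphere slice profile carries ripple at the scale of
#' individual van der Waals spheres that is below the method's physical
#' resolution. Each reported minimum is the central slice of its plateau.
#'
#' @param profile output of [radius_profile()].
#' @param min_prominence minimum prominence, Angstrom.
#' @param tol equality tolerance for plateau merging, Angstrom.
#' @return tibble subset of `profile` rows at local minima.
#' @export
profile_minima <- function(profile, min_prominence = 0.15, tol = 1e-6) {
  r <- profile$radius_mean
  run_id <- cumsum(c(TRUE, diff(is.na(r)) != 0))
  keep_rows <- integer(0)
  for (rid in unique(run_id[!is.na(r)])) {
    idx <- which(run_id == rid)
    if (length(idx) < 3) next
    v <- r[idx]
    seg <- cumsum(c(TRUE, abs(diff(v)) > tol))
    vals <- v[!duplicated(seg)]
    if (length(vals) < 3) next
    for (s in 2:(length(vals) - 1)) {
      if (vals[s] < vals[s - 1] && vals[s] < vals[s + 1]) {
        # prominence: climb outward to the nearest higher turning points
        left <- vals[seq_len(s - 1)]
        right <- vals[(s + 1):length(vals)]
        up_l <- cummax_turn(rev(left), vals[s])
        up_r <- cummax_turn(right, vals[s])
        if (min(up_l, up_r) - vals[s] < min_prominence) next
        members <- idx[seg == s]
        keep_rows <- c(keep_rows, members[ceiling(length(members) / 2)])
      }
    }
  }
  profile[keep_rows, ]
}

# Highest value reached walking outward from a minimum before descending
# below the minimum again (or hitting the run end).
cummax_turn <- function(v, floor_val) {
  top <- floor_val
  for (x in v) {
    if (x < floor_val) break
    if (x > top) top <- x
  }
  top
}
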