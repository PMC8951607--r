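# Shared fixture builders. Everything is generated in code; no data files.

flat_tube <- function(...) {
  build_ideal_nanotube(nanotube_spec(zigzag_angle = 0, include_backbone = FALSE,
                                     ...))
}

ca_tube <- function(...) {
  build_ideal_nanotube(nanotube_spec(include_backbone = FALSE, ...))
}

# regular n-gon in the xy plane, radius R, optional rigid transform
octagon <- function(n = 8, R = 4.8, center = c(0, 0, 0)) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  sweep(cbind(R * cos(phi), R * sin(phi), rep(0, n)), 2, center, "+")
}

rot_x <- function(deg) scpntools:::rotation_matrix(c(1, 0, 0), deg)

normalize <- scpntools:::normalize

# apply a rigid motion (rotation matrix + translation) to all coordinates
transform_frame <- function(frame, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- frame_coords(frame) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

transform_traj <- function(traj, R = diag(3), shift = c(0, 0, 0)) {
  for (t in seq_len(n_frames(traj))) {
    traj$coords[t, , ] <- sweep(traj$coords[t, , , drop = TRUE] %*% t(R),
                                2, shift, "+")
  }
  traj
}

# static trajectory: the same frame replicated
static_traj <- function(frame, nf = 3, dt = 1) {
  frames <- lapply(seq_len(nf), function(i) {
    attr(frame, "time") <- (i - 1) * dt
    frame
  })
  trajectory_from_frames(frames)
}

# minimal hand-built H-bond records table for lifetime tests
make_records <- function(frames_present, n_frames, dt = 1, bond_id = 1L) {
  out <- tibble::tibble(frame = frames_present,
                        donor = bond_id, hydrogen = bond_id + 1000L,
                        acceptor = bond_id + 2000L,
                        class = "cp_cp", backbone = TRUE,
                        donor_ring = 1L, acceptor_ring = 2L)
  attr(out, "frames") <- seq_len(n_frames)
  attr(out, "dt") <- dt
  out
}

# parse a topology from inline text
topology_from_text <- function(lines) {
  f <- tempfile(fileext = ".itp")
  on.exit(unlink(f))
  writeLines(lines, f)
  read_topology(f)
}
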