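test_that("ring centre is the centroid and behaves under translation", {
  oct <- octagon()
  expect_equal(ring_center(oct), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ring_center(octagon(center = c(1, 2, 3))), c(1, 2, 3),
               tolerance = 1e-12)
  set.seed(1)
  pts <- matrix(rnorm(24), ncol = 3)
  expect_equal(ring_center(pts), colMeans(pts))
  expect_error(ring_center(pts[1:2, ]), ">= 3")
})

test_that("alternating cross-product normal matches planar and rotated rings", {
  oct <- octagon()
  expect_equal(ring_normal(oct), c(0, 0, 1), tolerance = 1e-12)
  R <- rot_x(30)
  n30 <- ring_normal(oct %*% t(R))
  expect_equal(scpntools:::vec_angle(n30, c(0, 0, 1)), 30, tolerance = 1e-9)
  expect_equal(scpntools:::vec_angle(n30, R %*% c(0, 0, 1)), 0, tolerance = 1e-6)
})

test_that("zigzag displacements cancel in the normal", {
  flat <- flat_tube(n_rings = 1)
  zig <- ca_tube(n_rings = 1, zigzag_angle = 1.4)
  n_f <- ring_normal(frame_coords(flat))
  n_z <- ring_normal(frame_coords(zig))
  expect_lt(max(abs(n_f - n_z)), 1e-9)
})

test_that("normal agrees with the SVD plane oracle on jittered fixtures", {
  set.seed(7)
  for (rep in 1:20) {
    xyz <- octagon() %*% t(rot_x(runif(1, -30, 30)))
    xyz <- xyz + matrix(rnorm(length(xyz), sd = 0.15), ncol = 3)
    n_eq <- ring_normal(xyz)
    sv <- svd(sweep(xyz, 2, colMeans(xyz)))
    n_svd <- sv$v[, 3]
    ang <- scpntools:::vec_angle(n_eq, n_svd)
    expect_lt(min(ang, 180 - ang), 0.5)
  }
})

test_that("normal is invariant under cyclic relabelling and reversal", {
  set.seed(3)
  xyz <- octagon() %*% t(rot_x(12)) + matrix(rnorm(24, sd = 0.2), ncol = 3)
  n0 <- ring_normal(xyz)
  for (shift in 1:7) {
    ni <- ring_normal(xyz[c((shift + 1):8, 1:shift), ])
    expect_equal(abs(sum(ni * n0)), 1, tolerance = 1e-9)
  }
  nr <- ring_normal(xyz[8:1, ])
  expect_equal(abs(sum(nr * n0)), 1, tolerance = 1e-9)
})

test_that("collinear points are rejected", {
  line <- cbind(1:8, 2 * (1:8), rep(0, 8))
  expect_error(ring_normal(line), "collinear")
})

test_that("plane projection is orthogonal and exact on flat rings", {
  flat <- octagon()
  expect_equal(project_to_plane(flat), sweep(flat, 2, colMeans(flat)),
               tolerance = 1e-12)
  set.seed(9)
  xyz <- octagon() + matrix(rnorm(24, sd = 0.4), ncol = 3)
  n <- ring_normal(xyz)
  rpp <- project_to_plane(xyz)
  expect_lt(max(abs(rpp %*% n)), 1e-9)
})

test_that("angular deviation is 180 degrees on a polygon and localizes a perturbation", {
  fr <- flat_tube(n_rings = 1)
  th <- angular_deviation(fr)
  expect_equal(th$theta, rep(180, 8), tolerance = 1e-5)
  # rotate residue 1 azimuthally by 5 degrees: its own deviation is half
  # the rotation (the centroid recentring splits it), while residues at
  # 90 degrees are essentially untouched (values frozen from a direct
  # hand computation on the perturbed octagon)
  xyz <- frame_coords(fr)
  phi <- atan2(xyz[1, 2], xyz[1, 1]) + 5 * pi / 180
  xyz[1, 1:2] <- 4.8 * c(cos(phi), sin(phi))
  fr2 <- fr
  fr2$x <- xyz[, 1]; fr2$y <- xyz[, 2]; fr2$z <- xyz[, 3]
  th2 <- angular_deviation(fr2)
  expect_equal(th2$theta[1], 177.5, tolerance = 1e-3)
  expect_lt(abs(th2$theta[3] - 180), 0.2)
  expect_lt(abs(th2$theta[7] - 180), 0.2)
})

test_that("radial deformation statistics follow the construction and jitter", {
  fr <- ca_tube()
  st <- static_traj(fr, 4)
  rd <- radial_deformation(st)
  expect_equal(rd$radial_sd, rep(0, nrow(rd)))
  expect_equal(rd$radial_mean, rep(4.8 * cos(1.4 * pi / 180), nrow(rd)),
               tolerance = 1e-9)
  # Gaussian jitter: sd grows with sigma, mean bias below sigma
  sigma <- 0.3
  tr <- simulate_trajectory(fr, motion_spec(n_frames = 400, tilt_common_amp = 0,
                                            tilt_noise_sigma = 0, lateral_D = 0,
                                            jitter_sigma = sigma, seed = 21))
  rdj <- radial_deformation(tr)
  expect_gt(mean(rdj$radial_sd), 0.1)
  expect_lt(max(abs(rdj$radial_mean - 4.8 * cos(1.4 * pi / 180))), sigma)
  # a single residue displaced outward shifts only its own mean
  fr3 <- fr
  i <- which(fr3$name == "CA")[1]
  r0 <- sqrt(fr3$x[i]^2 + fr3$y[i]^2)
  fr3$x[i] <- fr3$x[i] * (r0 + 1) / r0
  fr3$y[i] <- fr3$y[i] * (r0 + 1) / r0
  rd3 <- radial_deformation(static_traj(fr3, 2))
  shift <- rd3$radial_mean - rd$radial_mean
  # the displaced residue gains ~1 A (less 1/8 through the centroid);
  # every other residue moves by at most the centroid shift
  expect_equal(shift[1], 1 - 1 / 8, tolerance = 0.01)
  expect_lt(max(abs(shift[-1])), 0.2)
})

test_that("centre-of-mass distances track the stacking", {
  fr <- build_ideal_nanotube(nanotube_spec())
  st <- static_traj(fr, 2)
  cd <- com_distance_series(st)
  expect_equal(unique(round(cd$distance, 9)), 4.8)
  # rigid translation leaves distances unchanged
  st2 <- transform_traj(st, shift = c(5, -3, 2))
  expect_equal(com_distance_series(st2)$distance, cd$distance, tolerance = 1e-9)
  # displacing one ring along the axis stretches one pair only
  fr4 <- fr
  top_ring <- fr4$ring == 8 & fr4$segment == "cp"
  fr4$z[top_ring] <- fr4$z[top_ring] + 1
  cd4 <- com_distance_series(static_traj(fr4, 1), ring_a = 7, ring_b = 8)
  expect_equal(cd4$distance, 5.8, tolerance = 1e-9)
})

test_that("tilt angles respond to rigid rotation and average down noise", {
  fr <- ca_tube()
  st <- static_traj(fr, 2)
  expect_equal(max(tilt_angles(st)$tilt), 0, tolerance = 1e-9)
  st10 <- transform_traj(st, R = rot_x(10))
  tl <- tilt_angles(st10)
  expect_equal(tl$tilt, rep(10, nrow(tl)), tolerance = 1e-6)
  # per-ring noise of 1 degree about a 10-degree common tilt: the tube
  # tilt stays within 3 sigma / sqrt(8) of the common value
  tr <- simulate_trajectory(fr, motion_spec(n_frames = 200, tilt_common_amp = 0,
                                            tilt_noise_sigma = 1, lateral_D = 0,
                                            jitter_sigma = 0, seed = 13))
  tr <- transform_traj(tr, R = rot_x(10))
  tl2 <- tilt_angles(tr)
  tube <- tl2$tilt[tl2$unit == "tube"]
  expect_lt(max(abs(tube - 10)), 3 * 1 / sqrt(8) + 0.2)
})

test_that("rmsd handles fitting, translation, and mismatches", {
  fr <- ca_tube()
  xyz <- frame_coords(fr)
  expect_equal(rmsd(xyz, xyz), 0, tolerance = 1e-9)
  shifted <- sweep(xyz, 2, c(3, 0, 4), "+")
  expect_equal(rmsd(shifted, xyz, fit = FALSE), 5, tolerance = 1e-9)
  expect_equal(rmsd(shifted, xyz, fit = TRUE), 0, tolerance = 1e-9)
  expect_error(rmsd(xyz[1:10, ], xyz), "mismatch")
})

test_that("superposition agrees with the bio3d reference", {
  set.seed(17)
  ref <- frame_coords(ca_tube(n_rings = 2))
  mob <- sweep(ref %*% t(rot_x(25)), 2, c(4, -2, 7), "+") +
    matrix(rnorm(length(ref), sd = 0.2), ncol = 3)
  ours <- rmsd(mob, ref, fit = TRUE)
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(ref)),
                                            as.vector(t(mob))))
  theirs <- bio3d::rmsd(as.vector(t(ref)), fitted)
  expect_equal(ours, theirs, tolerance = 1e-3)   # bio3d rounds to 3 decimals
})

test_that("rmsf of pure i.i.d. jitter matches the closed form", {
  fr <- ca_tube()
  sigma <- 0.5
  tr <- simulate_trajectory(fr, motion_spec(n_frames = 3000,
                                            tilt_common_amp = 0,
                                            tilt_noise_sigma = 0, lateral_D = 0,
                                            jitter_sigma = sigma, seed = 31))
  rf <- rmsf(tr, fit = FALSE)
  expect_lt(abs(mean(rf$rmsf) / (sigma * sqrt(3)) - 1), 0.05)
  # identical frames: zero fluctuation
  rf0 <- rmsf(static_traj(fr, 5))
  expect_equal(max(rf0$rmsf), 0, tolerance = 1e-9)
})

test_that("geometry observables are invariant under rigid motion", {
  fr <- build_ideal_nanotube(nanotube_spec())
  st <- static_traj(fr, 2)
  R <- rot_x(35) %*% scpntools:::rotation_matrix(c(0, 0, 1), 110)
  st2 <- transform_traj(st, R = R, shift = c(10, -4, 6))
  a <- radial_deformation(st); b <- radial_deformation(st2)
  expect_equal(b$radial_mean, a$radial_mean, tolerance = 1e-9)
  expect_equal(abs(b$delta_mean), abs(a$delta_mean), tolerance = 1e-9)
  expect_equal(b$theta_mean, a$theta_mean, tolerance = 1e-5)
  # hydrogen-bond counts too
  hb_a <- find_hbonds(get_frame(st, 1))
  hb_b <- find_hbonds(get_frame(st2, 1))
  expect_equal(nrow(hb_b), nrow(hb_a))
})
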