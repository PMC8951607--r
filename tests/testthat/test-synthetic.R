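test_that("ideal flat nanotube matches its construction parameters", {
  fr <- flat_tube()
  expect_equal(nrow(fr), 64)
  rg <- ring_geometry(fr)
  rings <- attr(rg, "rings")
  expect_equal(as.matrix(rings[, c("nx", "ny", "nz")]),
               matrix(rep(c(0, 0, 1), each = 8), ncol = 3,
                      dimnames = list(NULL, c("nx", "ny", "nz"))),
               tolerance = 1e-12)
  expect_equal(rg$delta, rep(0, 64), tolerance = 1e-9)
  expect_equal(rg$radial, rep(4.8, 64), tolerance = 1e-9)
  # consecutive ring c.o.m. distances equal the spacing exactly
  cd <- com_distance_series(static_traj(fr, 1))
  expect_equal(cd$distance, rep(4.8, 7), tolerance = 1e-9)
})

test_that("zigzag construction angle is recovered exactly", {
  for (zz in c(1.4, 2.8)) {
    fr <- ca_tube(zigzag_angle = zz)
    d <- delta_angle(fr)
    expect_equal(abs(d$delta), rep(zz, nrow(d)), tolerance = 1e-6)
    # sign alternates around the ring and sums to zero
    expect_equal(sign(d$delta), rep(c(1, -1), length.out = nrow(d)))
    sums <- tapply(d$delta, d$ring, sum)
    expect_true(all(abs(sums) < 1e-9))
    # projected radius follows the closed form R cos(delta)
    rg <- ring_geometry(fr)
    expect_equal(rg$radial, rep(4.8 * cos(zz * pi / 180), nrow(rg)),
                 tolerance = 1e-9)
  }
})

test_that("spec invariants are enforced", {
  expect_error(nanotube_spec(n_residues = 7), "even")
  expect_error(nanotube_spec(ring_radius = -1), "ring_radius")
  expect_error(nanotube_spec(spacing = 0), "spacing")
  expect_error(motion_spec(tilt_noise_sigma = -1), "sigmas")
  expect_error(motion_spec(lateral_D = -0.1), "lateral_D")
})

test_that("generator is bit-reproducible for a fixed seed", {
  fr <- ca_tube(n_rings = 3)
  m <- motion_spec(n_frames = 20, tilt_common_amp = 5, tilt_noise_sigma = 1,
                   lateral_D = 0.01, jitter_sigma = 0.2, seed = 42)
  t1 <- simulate_trajectory(fr, m)
  t2 <- simulate_trajectory(fr, m)
  expect_identical(t1$coords, t2$coords)
  t3 <- simulate_trajectory(fr, motion_spec(n_frames = 20, seed = 43))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("zero-motion trajectory is static and ground truth re-derives tilts", {
  fr <- ca_tube(n_rings = 3)
  tr <- simulate_trajectory(fr, motion_spec(n_frames = 5, tilt_common_amp = 0,
                                            tilt_noise_sigma = 0, lateral_D = 0,
                                            jitter_sigma = 0))
  for (t in 2:5) expect_equal(tr$coords[t, , ], tr$coords[1, , ])
  # with motion but no jitter, measured tilts equal |true tilts| exactly
  tr2 <- simulate_trajectory(fr, motion_spec(n_frames = 50, tilt_common_amp = 8,
                                             tilt_noise_sigma = 2, lateral_D = 0,
                                             jitter_sigma = 0, seed = 5))
  tl <- tilt_angles(tr2)
  tl <- tl[tl$unit != "tube", ]
  gt <- tr2$ground_truth$ring_tilts
  gt$unit <- as.character(gt$ring)
  m <- dplyr::inner_join(tl, gt[, c("frame", "unit", "tilt_true")],
                         by = c("frame", "unit"))
  expect_equal(m$tilt, abs(m$tilt_true), tolerance = 1e-6)
})

test_that("per-ring tilt series coincide when tilt noise is zero", {
  fr <- ca_tube(n_rings = 4)
  tr <- simulate_trajectory(fr, motion_spec(n_frames = 30, tilt_common_amp = 6,
                                            tilt_noise_sigma = 0, lateral_D = 0,
                                            jitter_sigma = 0, seed = 2))
  tl <- tilt_angles(tr)
  wide <- tidyr::pivot_wider(tl[tl$unit != "tube", c("frame", "unit", "tilt")],
                             names_from = "unit", values_from = "tilt")
  wide$frame <- NULL
  for (k in 2:ncol(wide)) expect_equal(wide[[k]], wide[[1]], tolerance = 1e-9)
})

test_that("lateral Brownian steps have the prescribed mean square", {
  fr <- ca_tube(n_rings = 2)
  D <- 0.001  # A^2/ps = 1 A^2/ns
  tr <- simulate_trajectory(fr, motion_spec(n_frames = 10000, dt_frame = 1,
                                            tilt_common_amp = 0,
                                            tilt_noise_sigma = 0,
                                            lateral_D = D, jitter_sigma = 0,
                                            seed = 11))
  gt <- tr$ground_truth$frames
  msd_step <- mean(diff(gt$lat_x)^2 + diff(gt$lat_y)^2)
  expect_lt(abs(msd_step / (4 * D * 1) - 1), 0.05)
})

test_that("channel water placement realizes the slot accounting", {
  fr8 <- build_ideal_nanotube(nanotube_spec())
  w8 <- place_channel_waters(fr8, "one_two")
  ow <- w8[w8$segment == "water" & w8$element == "O", ]
  expect_equal(nrow(ow), 24)  # 8 planes + 7 gaps x 2 + 2 mouths
  expect_true(all(sqrt(ow$x^2 + ow$y^2) <= 1.5))
  fr2 <- build_ideal_nanotube(nanotube_spec(n_rings = 2))
  w2 <- place_channel_waters(fr2, "one_two")
  expect_equal(sum(w2$segment == "water" & w2$element == "O"), 6)
  w23 <- place_channel_waters(fr8, "two_three")
  ow23 <- w23[w23$segment == "water" & w23$element == "O", ]
  expect_equal(nrow(ow23), 8 * 2 + 7 * 3 + 2 * 2)
  expect_true(all(sqrt(ow23$x^2 + ow23$y^2) <= 1.5))
  expect_error(place_channel_waters(flat_tube(n_rings = 1)), ">= 2 rings")
})

test_that("membrane proxy is inert unless asked for and symmetric", {
  fr <- build_ideal_nanotube(nanotube_spec())
  expect_identical(build_membrane_proxy(fr, 0), fr)
  frl <- build_membrane_proxy(fr, 16)
  lip <- frl[frl$segment == "lipid", ]
  expect_equal(nrow(lip), 32)
  # slabs symmetric about the tube midplane
  mid <- mean(range(fr$z[fr$name == "CA"]))
  expect_equal(mean(lip$z), mid, tolerance = 1e-9)
  # tilt reference unchanged: the static tube is still untilted
  tl <- tilt_angles(static_traj(frl, 2))
  expect_equal(max(tl$tilt), 0, tolerance = 1e-9)
})

test_that("a lipid head placed along a side-chain N-H axis forms one CP-lipid bond", {
  fr <- build_ideal_nanotube(nanotube_spec(n_rings = 2,
                                           include_sidechain_donor = TRUE))
  h <- fr[fr$name == "HE1", ][1, ]
  nn <- fr[fr$atom_id == h$donor_to, ]
  u <- normalize(c(h$x - nn$x, h$y - nn$y, h$z - nn$z))
  head_pos <- c(h$x, h$y, h$z) + 1.9 * u   # N...O = 2.9 along the N-H axis
  lip <- tibble::tibble(atom_id = max(fr$atom_id) + 1L, name = "OH",
                        element = "O", resid = max(fr$resid) + 1L,
                        resname = "LIP", ring = NA_integer_, segment = "lipid",
                        backbone = FALSE, donor_to = NA_integer_,
                        acceptor = TRUE, x = head_pos[1], y = head_pos[2],
                        z = head_pos[3])
  frl <- new_frame(dplyr::bind_rows(tibble::as_tibble(fr), lip))
  hb <- find_hbonds(frl)
  expect_equal(sum(hb$class == "cp_lipid"), 1)
})
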