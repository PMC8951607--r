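#' Specification of an idealized cyclic peptide nanotube
#'
#' Describes the geometry of a stack of D,L-alpha cyclic peptide (CP) rings.
#' The defaults correspond to the canonical transmembrane 8-ring octapeptide
#' tube: eight 8-residue rings of radius 4.8 Angstrom stacked every 4.8
#' Angstrom in antiparallel (beta-sheet-like) registry, with the backbone
#' amide N-H and C=O groups perpendicular to the ring planes so that each
#' ring-ring interface can form eight backbone hydrogen bonds.
#'
#' @param n_rings number of stacked rings.
#' @param n_residues residues per ring; must be even (D,L alternation) and
#'   at least 6 so the plane-fit sum in [ring_normal()] is well conditioned.
#' @param ring_radius distance from ring centre to each C-alpha, Angstrom.
#' @param spacing inter-ring (rise) distance, Angstrom.
#' @param zigzag_angle out-of-plane angle (degrees) of each C-alpha;
#'   alternates in sign around the ring (the D,L zigzag). Each C-alpha sits
#'   at distance `ring_radius` from the centre, `ring_radius*sin(zigzag)`
#'   off the plane.
#' @param registry `"antiparallel"` (default) or `"parallel"` stacking.
#' @param include_backbone add amide N, H, C, O atoms per residue, aligned
#'   with the tube axis, alternating direction residue-to-residue.
#' @param include_sidechain_donor add an indole-like side-chain N-H
#'   pseudo-group per residue, pointing radially outward.
#' @return an object of class `nanotube_spec`.
#' @export
#' @examples
#' nanotube_spec(zigzag_angle = 0)
nanotube_spec <- function(n_rings = 8, n_residues = 8, ring_radius = 4.8,
                          spacing = 4.8, zigzag_angle = 1.4,
                          registry = c("antiparallel", "parallel"),
                          include_backbone = TRUE,
                          include_sidechain_donor = FALSE) {
  registry <- match.arg(registry)
  if (n_rings < 1) stop("n_rings must be >= 1")
  if (n_residues %% 2 != 0)
    stop("n_residues must be even: D,L alternation (and the zigzag) ",
         "requires an even ring size")
  if (n_residues < 6) stop("n_residues must be >= 6")
  if (ring_radius <= 0) stop("ring_radius must be > 0")
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(
    n_rings = as.integer(n_rings), n_residues = as.integer(n_residues),
    ring_radius = ring_radius, spacing = spacing,
    zigzag_angle = zigzag_angle, registry = registry,
    include_backbone = isTRUE(include_backbone),
    include_sidechain_donor = isTRUE(include_sidechain_donor)
  ), class = "nanotube_spec")
}

#' @export
print.nanotube_spec <- function(x, ...) {
  cat(sprintf("<nanotube_spec> %d rings x %d residues, radius %.2f A, spacing %.2f A\n",
              x$n_rings, x$n_residues, x$ring_radius, x$spacing))
  cat(sprintf("  zigzag %.2f deg, %s registry, backbone: %s, side-chain donor: %s\n",
              x$zigzag_angle, x$registry, x$include_backbone, x$include_sidechain_donor))
  invisible(x)
}

#' Specification of synthetic nanotube motion
#'
#' Parameters of the rigid-body dynamics imposed on an ideal nanotube by
#' [simulate_trajectory()]: a common AR(1)-smoothed tilt of the whole tube
#' about the membrane plane, independent per-ring tilt noise, 2D Brownian
#' lateral diffusion of the tube in the membrane plane, and i.i.d. Gaussian
#' positional jitter. With a fixed `seed` the trajectory is bit-reproducible.
#'
#' @param n_frames number of frames.
#' @param dt_frame frame spacing, ps.
#' @param tilt_common_amp stationary standard deviation of the common
#'   (whole-tube) tilt signal, degrees.
#' @param tilt_noise_sigma standard deviation of independent per-ring tilt
#'   noise, degrees.
#' @param lateral_D lateral diffusion coefficient of the tube centre,
#'   Angstrom^2/ps (0.001 A^2/ps = 1 A^2/ns, typical of a transmembrane
#'   peptide assembly).
#' @param jitter_sigma per-coordinate Gaussian noise on every atom, Angstrom.
#' @param seed integer RNG seed.
#' @return an object of class `motion_spec`.
#' @export
motion_spec <- function(n_frames = 1000, dt_frame = 2, tilt_common_amp = 10,
                        tilt_noise_sigma = 2, lateral_D = 0.001,
                        jitter_sigma = 0.3, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (dt_frame <= 0) stop("dt_frame must be > 0")
  if (tilt_common_amp < 0 || tilt_noise_sigma < 0 || jitter_sigma < 0)
    stop("amplitudes and sigmas must be >= 0")
  if (lateral_D < 0) stop("lateral_D must be >= 0")
  structure(list(
    n_frames = as.integer(n_frames), dt_frame = dt_frame,
    tilt_common_amp = tilt_common_amp, tilt_noise_sigma = tilt_noise_sigma,
    lateral_D = lateral_D, jitter_sigma = jitter_sigma,
    seed = as.integer(seed)
  ), class = "motion_spec")
}

#' @export
print.motion_spec <- function(x, ...) {
  cat(sprintf("<motion_spec> %d frames @ %.3g ps; tilt %g deg (noise %g), D = %g A^2/ps, jitter %g A, seed %d\n",
              x$n_frames, x$dt_frame, x$tilt_common_amp, x$tilt_noise_sigma,
              x$lateral_D, x$jitter_sigma, x$seed))
  invisible(x)
}
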