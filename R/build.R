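# Geometry constants of the ideal amide unit (Angstrom). The N and C atoms
# sit AMIDE_OFFSET off the ring plane along the amide axis so that the
# interface donor-acceptor distance is spacing - 2*AMIDE_OFFSET - CO_LEN
# (2.90 A at the default 4.8 A spacing), a beta-sheet-like value well
# inside the default geometric H-bond criterion.
NH_LEN <- 1.00
CO_LEN <- 1.23
AMIDE_OFFSET <- 0.335

#' Build an ideal cyclic peptide nanotube
#'
#' Constructs one static frame of an idealized D,L-alpha cyclic peptide
#' nanotube from a [nanotube_spec()]. C-alpha atoms of ring k lie on a
#' regular polygon centred at z = (k-1)*spacing, each at distance
#' `ring_radius` from the centre with an alternating out-of-plane (zigzag)
#' angle. If `include_backbone`, each residue carries an amide N-H and C=O
#' unit aligned with the tube axis; the unit direction alternates
#' residue-to-residue so that at every ring-ring interface each of the
#' `n_residues` columns pairs one donor with one acceptor (the antiparallel,
#' beta-sheet-like registry), allowing exactly `n_residues` backbone
#' hydrogen bonds per interface. In `"parallel"` registry all amides of a
#' ring point the same way.
#'
#' @param spec a [nanotube_spec()].
#' @return a [new_frame()] tibble of atoms.
#' @export
#' @examples
#' frame <- build_ideal_nanotube(nanotube_spec())
#' nrow(frame[frame$name == "CA", ])  # 64
build_ideal_nanotube <- function(spec = nanotube_spec()) {
  stopifnot(inherits(spec, "nanotube_spec"))
  n <- spec$n_residues
  R <- spec$ring_radius
  delta <- deg2rad(spec$zigzag_angle)
  r_in <- R * cos(delta)       # in-plane radius
  dz <- R * sin(delta)         # out-of-plane offset

  rows <- list()
  aid <- 0L
  for (k in seq_len(spec$n_rings)) {
    z0 <- (k - 1) * spec$spacing
    for (j in seq_len(n)) {
      phi <- 2 * pi * (j - 1) / n
      sgn <- (-1)^(j - 1)                      # zigzag sign
      ori <- if (spec$registry == "antiparallel") (-1)^(j - 1) else 1
      xj <- r_in * cos(phi); yj <- r_in * sin(phi)
      resid <- (k - 1L) * n + j
      add <- function(name, element, x, y, z, backbone, donor_to = NA_integer_,
                      acceptor = FALSE) {
        aid <<- aid + 1L
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          atom_id = aid, name = name, element = element, resid = resid,
          resname = "TRP", ring = k, segment = "cp", backbone = backbone,
          donor_to = donor_to, acceptor = acceptor, x = x, y = y, z = z)
        aid
      }
      add("CA", "C", xj, yj, z0 + sgn * dz, backbone = TRUE)
      if (spec$include_backbone) {
        # ori = +1: C=O points up (+z), N-H points down; ori = -1 mirrored.
        id_n <- add("N", "N", xj, yj, z0 - ori * AMIDE_OFFSET, backbone = TRUE)
        add("H", "H", xj, yj, z0 - ori * (AMIDE_OFFSET + NH_LEN),
            backbone = TRUE, donor_to = id_n)
        add("C", "C", xj, yj, z0 + ori * AMIDE_OFFSET, backbone = TRUE)
        add("O", "O", xj, yj, z0 + ori * (AMIDE_OFFSET + CO_LEN),
            backbone = TRUE, acceptor = TRUE)
      }
      if (spec$include_sidechain_donor) {
        ux <- cos(phi); uy <- sin(phi)
        id_ne <- add("NE1", "N", (R + 1.8) * ux, (R + 1.8) * uy, z0,
                     backbone = FALSE)
        add("HE1", "H", (R + 2.8) * ux, (R + 2.8) * uy, z0,
            backbone = FALSE, donor_to = id_ne)
      }
    }
  }
  new_frame(dplyr::bind_rows(rows), time = 0, box = NULL, spec = spec)
}

# z positions of the ring planes of a frame (mean C-alpha z per ring),
# and the mean inter-ring spacing.
ring_plane_z <- function(frame) {
  coords <- ring_ca_coords(frame)
  z <- vapply(coords, function(m) mean(m[, 3]), numeric(1))
  sort(unname(z))
}

#' Place idealized channel waters
#'
#' Adds single-file water molecules on the tube axis following the
#' idealized axial occupancy patterns: `"one_two"` places one molecule at
#' each ring plane and two in each inter-ring gap, `"two_three"` places two
#' and three respectively. One additional molecule per channel mouth
#' (`"one_two"`) or two (`"two_three"`) sit just outside the terminal ring
#' planes, inside the default channel bounds. For the default 8-ring tube
#' the `"one_two"` pattern totals 8 + 14 + 2 = 24 molecules.
#'
#' @param frame a `nanotube_frame` with at least 2 rings.
#' @param pattern `"one_two"` or `"two_three"`.
#' @return the frame with water atoms (resname `"SOL"`; atoms OW, HW1, HW2)
#'   appended.
#' @export
place_channel_waters <- function(frame, pattern = c("one_two", "two_three")) {
  pattern <- match.arg(pattern)
  z <- ring_plane_z(frame)
  if (length(z) < 2) stop("channel water placement needs >= 2 rings")
  s <- mean(diff(z))
  n_plane <- if (pattern == "one_two") 1L else 2L
  n_gap <- if (pattern == "one_two") 2L else 3L
  n_mouth <- n_plane

  spread <- function(z0, m) {
    # m water z-positions centred on z0, within +/- s/8 of it
    if (m == 1) z0 else z0 + seq(-s / 8, s / 8, length.out = m)
  }
  tight <- function(z0, m) if (m == 1) z0 else z0 + seq(-0.3, 0.3, length.out = m)
  zw <- c(
    unlist(lapply(z, tight, m = n_plane)),
    unlist(lapply(utils::head(z, -1) + s / 2, spread, m = n_gap)),
    tight(z[1] - 3 * s / 8, n_mouth),
    tight(z[length(z)] + 3 * s / 8, n_mouth)
  )

  aid <- max(frame$atom_id)
  rid <- max(frame$resid)
  wat <- purrr::map_dfr(seq_along(zw), function(i) {
    o <- aid + (i - 1L) * 3L + 1L
    tibble::tibble(
      atom_id = o + 0:2,
      name = c("OW", "HW1", "HW2"),
      element = c("O", "H", "H"),
      resid = rid + i,
      resname = "SOL", ring = NA_integer_, segment = "water",
      backbone = FALSE,
      donor_to = c(NA_integer_, o, o),
      acceptor = c(TRUE, FALSE, FALSE),
      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = zw[i] + c(0, 0, 0))
  })
  out <- dplyr::bind_rows(tibble::as_tibble(frame), wat)
  new_frame(out, time = attr(frame, "time") %||% 0,
            box = frame_box(frame), spec = frame_spec(frame))
}

#' Add a planar pseudo-lipid membrane proxy
#'
#' Places two planar slabs of single-site pseudo-lipid particles (each an
#' acceptor-bearing headgroup oxygen, resname `"LIP"`) at the z levels of
#' the terminal ring planes, symmetric about the tube midplane, on an
#' annular grid around the tube. Particles overlapping nanotube atoms
#' (within 2 Angstrom) are pushed radially outward with a warning. This is
#' a synthetic stand-in for a phospholipid bilayer, sufficient for
#' CP-lipid hydrogen-bond accounting and tilt-reference tests; it has no
#' chain detail.
#'
#' @param frame a `nanotube_frame`.
#' @param n_per_leaflet number of pseudo-lipids per leaflet; 0 leaves the
#'   frame unchanged.
#' @return the frame with lipid particles appended.
#' @export
build_membrane_proxy <- function(frame, n_per_leaflet = 16) {
  if (n_per_leaflet == 0) return(frame)
  z <- ring_plane_z(frame)
  zlev <- c(z[1], z[length(z)])
  spec <- frame_spec(frame)
  r0 <- (spec$ring_radius %||% 4.8) + 8
  cp_xyz <- frame_coords(frame)

  mk_leaflet <- function(zl, n) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    rad <- r0 + 4 * ((seq_len(n) - 1) %/% 12)   # concentric shells
    x <- rad * cos(ang); y <- rad * sin(ang)
    for (i in seq_len(n)) {
      d2 <- (cp_xyz[, 1] - x[i])^2 + (cp_xyz[, 2] - y[i])^2 + (cp_xyz[, 3] - zl)^2
      while (any(d2 < 4)) {
        warning("pseudo-lipid overlapped nanotube atoms; re-placed outward")
        rr <- sqrt(x[i]^2 + y[i]^2) + 2
        x[i] <- rr * cos(ang[i]); y[i] <- rr * sin(ang[i])
        d2 <- (cp_xyz[, 1] - x[i])^2 + (cp_xyz[, 2] - y[i])^2 + (cp_xyz[, 3] - zl)^2
      }
    }
    cbind(x, y, rep(zl, n))
  }
  pos <- rbind(mk_leaflet(zlev[1], n_per_leaflet),
               mk_leaflet(zlev[2], n_per_leaflet))
  aid <- max(frame$atom_id)
  rid <- max(frame$resid)
  lip <- tibble::tibble(
    atom_id = aid + seq_len(nrow(pos)),
    name = "OH", element = "O", resid = rid + seq_len(nrow(pos)),
    resname = "LIP", ring = NA_integer_, segment = "lipid",
    backbone = FALSE, donor_to = NA_integer_, acceptor = TRUE,
    x = pos[, 1], y = pos[, 2], z = pos[, 3])
  out <- dplyr::bind_rows(tibble::as_tibble(frame), lip)
  new_frame(out, time = attr(frame, "time") %||% 0,
            box = frame_box(frame), spec = spec)
}
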