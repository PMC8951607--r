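# Kabsch optimal rotation aligning `mob` onto `ref` (both n x 3,
# centred by the caller). Returns the 3 x 3 rotation matrix.
kabsch_rotation <- function(mob, ref) {
  H <- t(mob) %*% ref
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# Superpose `mob` onto `ref` (n x 3 each): centre, rotate, translate.
superpose <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  Rm <- kabsch_rotation(sweep(mob, 2, cm), sweep(ref, 2, cr))
  sweep(sweep(mob, 2, cm) %*% Rm, 2, cr, "+")
}

#' Root-mean-square deviation between two structures
#'
#' @param xyz,ref n x 3 coordinate matrices (or `nanotube_frame`s) with
#'   matching atom order.
#' @param selection optional integer row indices used both for the fit and
#'   the deviation.
#' @param fit if TRUE (default), optimal rigid-body superposition (Kabsch)
#'   is applied before measuring; if FALSE the raw deviation is returned.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(xyz, ref, selection = NULL, fit = TRUE) {
  if (inherits(xyz, "nanotube_frame")) xyz <- frame_coords(xyz)
  if (inherits(ref, "nanotube_frame")) ref <- frame_coords(ref)
  if (!is.null(selection)) {
    xyz <- xyz[selection, , drop = FALSE]
    ref <- ref[selection, , drop = FALSE]
  }
  if (nrow(xyz) != nrow(ref)) stop("atom-count mismatch between structures")
  if (fit) xyz <- superpose(xyz, ref)
  sqrt(mean(rowSums((xyz - ref)^2)))
}

#' Per-atom root-mean-square fluctuation over a trajectory
#'
#' Each frame is superposed (Kabsch) onto the time-mean structure — itself
#' obtained after superposing all frames onto the first — and the RMSF is
#' the root-mean-square distance of each atom from its time-mean position.
#'
#' @param traj a `nanotube_trajectory`.
#' @param selection integer atom indices (default: all peptide atoms).
#' @param fit superpose frames before measuring (default TRUE).
#' @param discard initial time (ps) to drop.
#' @return tibble (atom_id, name, resid, ring, rmsf), Angstrom.
#' @export
rmsf <- function(traj, selection = NULL, fit = TRUE, discard = 0) {
  atoms <- traj$atoms
  if (is.null(selection)) selection <- which(atoms$segment == "cp")
  idx <- which(traj$time >= discard)
  nf <- length(idx)
  get <- function(t) traj$coords[t, selection, , drop = TRUE]
  ref <- get(idx[1])
  frames <- lapply(idx, function(t) {
    x <- get(t)
    if (fit) superpose(x, ref) else x
  })
  mean_xyz <- Reduce(`+`, frames) / nf
  if (fit) frames <- lapply(frames, superpose, ref = mean_xyz)
  dev2 <- Reduce(`+`, lapply(frames, function(x) rowSums((x - mean_xyz)^2))) / nf
  tibble::tibble(atom_id = atoms$atom_id[selection],
                 name = atoms$name[selection],
                 resid = atoms$resid[selection],
                 ring = atoms$ring[selection],
                 rmsf = sqrt(dev2))
}
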