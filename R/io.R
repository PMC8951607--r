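#' Write a structure file (PDB or GRO)
#'
#' PDB files are written through bio3d (v3.3 fixed columns, one chain per
#' ring); GRO files are written directly in the fixed-width GROMACS format
#' (nm, 3 decimals). Both round-trip through [read_structure()] with
#' coordinate error bounded by the format precision (0.001 A for PDB,
#' 0.01 A for GRO).
#'
#' @param frame a `nanotube_frame`.
#' @param path output file; format inferred from the extension when
#'   `format = NULL`.
#' @param format `"pdb"`, `"gro"`, or NULL.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("pdb", "gro")) stop("unsupported structure format: ", format)
  if (nrow(frame) == 0) stop("empty frame")
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = as.vector(t(frame_coords(frame))),
                     resno = frame$resid, resid = frame$resname,
                     eleno = frame$atom_id, elety = frame$name,
                     chain = chain_letters(frame), elesy = frame$element)
  } else {
    xyz <- frame_coords(frame) / 10   # Angstrom -> nm
    box <- frame_box(frame) %||% (apply(frame_coords(frame), 2, function(v) diff(range(v)) + 20))
    lines <- c(
      "nanotube structure",
      sprintf("%5d", nrow(frame)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              frame$resid %% 100000, substr(frame$resname, 1, 5),
              substr(frame$name, 1, 5), frame$atom_id %% 100000,
              xyz[, 1], xyz[, 2], xyz[, 3]),
      sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10))
    writeLines(lines, path)
  }
  invisible(path)
}

chain_letters <- function(frame) {
  ch <- rep("X", nrow(frame))
  cp <- frame$segment == "cp" & !is.na(frame$ring)
  ch[cp] <- LETTERS[((frame$ring[cp] - 1) %% 26) + 1]
  ch[frame$segment == "water"] <- "W"
  ch[frame$segment == "lipid"] <- "L"
  ch
}

#' Read a structure file (PDB or GRO)
#'
#' Atom metadata (segment, ring, backbone, donor/acceptor flags) is
#' reconstructed from residue names and chains: `SOL`/`HOH` atoms become
#' water, `LIP` lipid, everything else peptide, with rings taken from the
#' PDB chain (or contiguous residue blocks of `n_residues` for GRO when a
#' `spec` is supplied).
#'
#' @param path input file.
#' @param format `"pdb"`, `"gro"`, or NULL to infer from the extension.
#' @param spec optional [nanotube_spec()] used to assign rings.
#' @return a `nanotube_frame`.
#' @export
read_structure <- function(path, format = NULL, spec = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "pdb") {
    p <- bio3d::read.pdb(path)
    a <- p$atom
    atoms <- tibble::tibble(
      atom_id = as.integer(a$eleno), name = a$elety,
      element = ifelse(is.na(a$elesy) | a$elesy == "",
                       substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
      resid = as.integer(a$resno), resname = a$resid,
      chain = a$chain, x = a$x, y = a$y, z = a$z)
  } else if (format == "gro") {
    lines <- readLines(path)
    nat <- as.integer(trimws(lines[2]))
    body <- lines[3:(2 + nat)]
    atoms <- tibble::tibble(
      atom_id = as.integer(substr(body, 16, 20)),
      name = trimws(substr(body, 11, 15)),
      resid = as.integer(substr(body, 1, 5)),
      resname = trimws(substr(body, 6, 10)),
      chain = NA_character_,
      x = 10 * as.numeric(substr(body, 21, 28)),
      y = 10 * as.numeric(substr(body, 29, 36)),
      z = 10 * as.numeric(substr(body, 37, 44)))
    atoms$element <- substr(atoms$name, 1, 1)
  } else stop("unsupported structure format: ", format)
  annotate_atoms(atoms, spec = spec)
}

# Rebuild analysis metadata from plain structure columns.
annotate_atoms <- function(atoms, spec = NULL, time = 0, box = NULL) {
  water <- atoms$resname %in% c("SOL", "HOH", "WAT", "SPC")
  lipid <- atoms$resname %in% c("LIP", "POPC")
  atoms$segment <- ifelse(water, "water", ifelse(lipid, "lipid", "cp"))
  atoms$backbone <- atoms$segment == "cp" &
    atoms$name %in% c("CA", "N", "H", "C", "O")
  atoms$acceptor <- atoms$element == "O"
  # ring from chain when present, else residue blocks of n_residues
  atoms$ring <- NA_integer_
  cp <- atoms$segment == "cp"
  if (!is.null(atoms$chain) && any(!is.na(atoms$chain[cp]))) {
    atoms$ring[cp] <- match(atoms$chain[cp], LETTERS)
  } else if (!is.null(spec)) {
    atoms$ring[cp] <- ((match(atoms$resid[cp], sort(unique(atoms$resid[cp]))) - 1) %/%
                         spec$n_residues) + 1L
  }
  # donor hydrogens: an H whose previous atom in file order is N or O
  atoms$donor_to <- NA_integer_
  h <- which(atoms$element == "H")
  prev <- pmax(h - 1L, 1L)
  heavy_prev <- atoms$element[prev] %in% c("N", "O")
  # water HW2 follows HW1; bond both to the OW two rows up
  hw2 <- atoms$name[h] %in% c("HW2", "HW3") & atoms$element[pmax(h - 2L, 1L)] == "O"
  atoms$donor_to[h[heavy_prev]] <- atoms$atom_id[prev[heavy_prev]]
  atoms$donor_to[h[hw2]] <- atoms$atom_id[pmax(h[hw2] - 2L, 1L)]
  atoms$chain <- NULL
  new_frame(atoms, time = time, box = box, spec = spec)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `nanotube_trajectory` with at least one frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (n_frames(traj) == 0) stop("empty trajectory")
  f1 <- get_frame(traj, 1)
  nf <- n_frames(traj); na <- nrow(traj$atoms)
  xyz <- matrix(NA_real_, nf, 3 * na)
  for (t in seq_len(nf)) xyz[t, ] <- as.vector(t(traj$coords[t, , , drop = TRUE]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = f1$resid, resid = f1$resname,
                   eleno = f1$atom_id, elety = f1$name,
                   chain = chain_letters(f1), elesy = f1$element)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' @param path input file.
#' @param spec optional [nanotube_spec()] for ring assignment.
#' @param dt frame spacing in ps used to build time stamps.
#' @return a `nanotube_trajectory`.
#' @export
read_trajectory <- function(path, spec = NULL, dt = 1) {
  p <- bio3d::read.pdb(path, multi = TRUE)
  a <- p$atom
  atoms <- tibble::tibble(
    atom_id = as.integer(a$eleno), name = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    resid = as.integer(a$resno), resname = a$resid, chain = a$chain,
    x = a$x, y = a$y, z = a$z)
  frame <- annotate_atoms(atoms, spec = spec)
  nf <- nrow(p$xyz)
  coords <- array(NA_real_, c(nf, nrow(atoms), 3))
  for (t in seq_len(nf)) coords[t, , ] <- matrix(p$xyz[t, ], ncol = 3, byrow = TRUE)
  new_trajectory(frame, coords, time = (seq_len(nf) - 1) * dt, spec = spec)
}

#' Write or read ground truth as a YAML sidecar
#'
#' Serializes the generator specs and the true per-frame centre and tilt
#' series of a synthetic trajectory, sufficient to re-derive every true
#' parameter.
#'
#' @param gt the `ground_truth` element of a synthetic trajectory.
#' @param path YAML file path.
#' @return `path` invisibly (write); the ground-truth list (read).
#' @export
write_ground_truth <- function(gt, path) {
  obj <- list(
    nanotube = unclass(gt$nanotube), motion = unclass(gt$motion),
    frames = as.list(gt$frames), ring_tilts = as.list(gt$ring_tilts))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  list(
    nanotube = do.call(nanotube_spec, obj$nanotube),
    motion = do.call(motion_spec, obj$motion),
    frames = tibble::as_tibble(obj$frames),
    ring_tilts = tibble::as_tibble(obj$ring_tilts))
}
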