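#' Construct a nanotube frame
#'
#' A frame is a tibble of atoms (one row per atom) carrying coordinates in
#' Angstrom plus the metadata the analysis functions rely on, with `time`
#' (ps) and optional orthorhombic `box` (edge lengths, Angstrom) attached
#' as attributes.
#'
#' Required columns: `atom_id`, `name`, `element`, `resid`, `resname`,
#' `ring` (integer or NA), `segment` (`"cp"`, `"water"`, `"lipid"`),
#' `backbone` (logical), `donor_to` (for hydrogens: `atom_id` of the bonded
#' heavy atom, else NA), `acceptor` (logical), `x`, `y`, `z`.
#'
#' @param atoms tibble with the columns listed above.
#' @param time frame time stamp, ps.
#' @param box length-3 numeric or NULL.
#' @param spec optional [nanotube_spec()] recorded for provenance.
#' @return a `nanotube_frame` (a tibble subclass).
#' @export
new_frame <- function(atoms, time = 0, box = NULL, spec = NULL) {
  needed <- c("atom_id", "name", "element", "resid", "resname", "ring",
              "segment", "backbone", "donor_to", "acceptor", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0)
    stop("atoms table lacks column(s): ", paste(missing, collapse = ", "))
  out <- tibble::as_tibble(atoms)
  attr(out, "time") <- time
  attr(out, "box") <- box
  attr(out, "spec") <- spec
  class(out) <- c("nanotube_frame", class(tibble::tibble()))
  out
}

#' Coordinates of a frame as a matrix
#'
#' @param frame a `nanotube_frame`.
#' @return n_atoms x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(frame) {
  as.matrix(frame[, c("x", "y", "z")])
}

set_frame_coords <- function(frame, xyz) {
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

frame_box <- function(frame) attr(frame, "box")
frame_spec <- function(frame) attr(frame, "spec")

#' @export
print.nanotube_frame <- function(x, ...) {
  cat(sprintf("<nanotube_frame> %d atoms (%s), t = %g ps\n",
              nrow(x),
              paste(sprintf("%s: %d", names(table(x$segment)), table(x$segment)),
                    collapse = ", "),
              attr(x, "time") %||% 0))
  NextMethod()
}

# Split the C-alpha coordinates of a frame into per-ring matrices,
# ordered by residue within each ring.
ring_ca_coords <- function(frame) {
  ca <- frame[frame$segment == "cp" & frame$name == "CA" & !is.na(frame$ring), ]
  if (nrow(ca) == 0) stop("frame contains no C-alpha atoms")
  ca <- ca[order(ca$ring, ca$resid), ]
  lapply(split(seq_len(nrow(ca)), ca$ring), function(i) {
    as.matrix(ca[i, c("x", "y", "z")])
  })
}
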