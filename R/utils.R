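#' @importFrom rlang %||% .data
#' @importFrom stats cor sd setNames
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix (right-handed).
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- normalize(axis)
  a <- deg2rad(angle)
  c1 <- cos(a); s1 <- sin(a); t1 <- 1 - c1
  matrix(c(
    c1 + u[1]^2 * t1,        u[1] * u[2] * t1 - u[3] * s1, u[1] * u[3] * t1 + u[2] * s1,
    u[2] * u[1] * t1 + u[3] * s1, c1 + u[2]^2 * t1,        u[2] * u[3] * t1 - u[1] * s1,
    u[3] * u[1] * t1 - u[2] * s1, u[3] * u[2] * t1 + u[1] * s1, c1 + u[3]^2 * t1
  ), nrow = 3, byrow = TRUE)
}

# Minimum-image convention for an orthorhombic box. `d` is an n x 3
# displacement matrix; box a length-3 vector of edge lengths (Angstrom),
# or NULL for a non-periodic system.
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# van der Waals radii (Angstrom) by element; Bondi values, generic fallback.
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  r <- unname(tab[element])
  r[is.na(r)] <- 1.50
  r
}

# Standard atomic masses (Da) by element symbol, for c.o.m. calculations.
element_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
  m <- unname(tab[element])
  m[is.na(m)] <- 1
  m
}

# Angle between two 3-vectors in degrees, numerically clamped.
vec_angle <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  rad2deg(acos(min(1, max(-1, ca))))
}

# Row-wise angle (degrees) between two n x 3 matrices.
vec_angle_rows <- function(A, B) {
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  rad2deg(acos(pmin(1, pmax(-1, num / den))))
}
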