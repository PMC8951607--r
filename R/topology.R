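#' Isotope masses for hydrogen isotope exchange
#'
#' Masses (Da) used by [apply_hie()]: protium, deuterium, quadium
#' (hydrogen-4), and hydrogen-7.
#'
#' @return named numeric vector.
#' @export
isotope_masses <- function() {
  c(H = 1.008, D = 2.014, Q = 4.026, H7 = 7.053)
}

WATER_MOL_NAMES <- c("SOL", "WAT", "HOH", "SPC", "SPCE", "TIP3", "TIP3P",
                     "TIP4", "TIP4P", "WATER")

is_water_mol <- function(name) toupper(name) %in% WATER_MOL_NAMES

#' Read a GROMOS/GROMACS-style topology (TOP/ITP dialect)
#'
#' Parses `[moleculetype]`, `[atoms]`, `[bonds]`, `[settles]` and
#' `[molecules]` sections; every other line is preserved verbatim so that
#' [write_topology()] round-trips the file byte-identically outside the
#' `[atoms]` mass column. `#include` directives are spliced in when the
#' referenced file exists next to the topology, otherwise kept verbatim
#' with a warning. A settle record implies the two O-H bonds of a
#' three-site water.
#'
#' @param path topology file.
#' @return an object of class `md_topology`: a list with `lines` (the full
#'   text), `atoms` (tibble: mol, id, type, resnr, resname, name, cgnr,
#'   charge, mass, line), `bonds` (tibble: mol, ai, aj, settle) and
#'   `system` (tibble: mol, count; one row per `[molecules]` entry, or one
#'   copy of each moleculetype when the section is absent).
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # resolve includes relative to the file, depth-first
  out <- character(0)
  for (ln in lines) {
    inc <- regmatches(ln, regexec("^\\s*#include\\s+\"([^\"]+)\"", ln))[[1]]
    if (length(inc) == 2) {
      target <- file.path(dirname(path), inc[2])
      if (file.exists(target)) {
        out <- c(out, readLines(target, warn = FALSE))
      } else {
        warning("include not found, kept verbatim: ", inc[2])
        out <- c(out, ln)
      }
    } else out <- c(out, ln)
  }
  parse_topology_lines(out, source = path)
}

parse_topology_lines <- function(lines, source = "<text>") {
  strip <- function(x) trimws(sub(";.*$", "", x))
  section <- ""
  mol <- NA_character_
  expect_molname <- FALSE
  atoms <- list(); bonds <- list(); sys <- list()
  for (i in seq_along(lines)) {
    code <- strip(lines[i])
    if (code == "") next
    hdr <- regmatches(code, regexec("^\\[\\s*(\\S+)\\s*\\]$", code))[[1]]
    if (length(hdr) == 2) {
      section <- tolower(hdr[2])
      expect_molname <- section == "moleculetype"
      next
    }
    fields <- strsplit(code, "\\s+")[[1]]
    if (expect_molname) {
      mol <- fields[1]
      expect_molname <- FALSE
      next
    }
    if (section == "atoms") {
      if (length(fields) < 8)
        stop(sprintf("malformed [atoms] line %d in %s: '%s'", i, source, lines[i]))
      mass <- suppressWarnings(as.numeric(fields[8]))
      charge <- suppressWarnings(as.numeric(fields[7]))
      if (is.na(mass) || is.na(charge))
        stop(sprintf("malformed [atoms] line %d in %s: '%s'", i, source, lines[i]))
      if (mass <= 0)
        stop(sprintf("non-positive mass on [atoms] line %d in %s", i, source))
      atoms[[length(atoms) + 1]] <- tibble::tibble(
        mol = mol %||% "MOL", id = as.integer(fields[1]), type = fields[2],
        resnr = as.integer(fields[3]), resname = fields[4], name = fields[5],
        cgnr = as.integer(fields[6]), charge = charge, mass = mass, line = i)
    } else if (section == "bonds") {
      bonds[[length(bonds) + 1]] <- tibble::tibble(
        mol = mol %||% "MOL", ai = as.integer(fields[1]),
        aj = as.integer(fields[2]), settle = FALSE)
    } else if (section == "settles") {
      ow <- as.integer(fields[1])
      bonds[[length(bonds) + 1]] <- tibble::tibble(
        mol = mol %||% "MOL", ai = ow, aj = ow + 1:2, settle = TRUE)
    } else if (section == "molecules") {
      sys[[length(sys) + 1]] <- tibble::tibble(mol = fields[1],
                                               count = as.integer(fields[2]))
    }
  }
  atoms <- if (length(atoms)) dplyr::bind_rows(atoms) else
    tibble::tibble(mol = character(), id = integer(), type = character(),
                   resnr = integer(), resname = character(), name = character(),
                   cgnr = integer(), charge = numeric(), mass = numeric(),
                   line = integer())
  bonds <- if (length(bonds)) dplyr::bind_rows(bonds) else
    tibble::tibble(mol = character(), ai = integer(), aj = integer(),
                   settle = logical())
  if (nrow(atoms) == 0) warning("no [atoms] parsed: empty topology")
  sys <- if (length(sys)) dplyr::bind_rows(sys) else
    tibble::tibble(mol = unique(atoms$mol), count = 1L)
  # validate bond indices
  for (m in unique(bonds$mol)) {
    ids <- atoms$id[atoms$mol == m]
    b <- bonds[bonds$mol == m, ]
    if (!all(c(b$ai, b$aj) %in% ids))
      stop("bond references unknown atom index in moleculetype ", m)
  }
  structure(list(lines = lines, atoms = atoms, bonds = bonds, system = sys),
            class = "md_topology")
}

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("<md_topology> %d moleculetype(s), %d atoms, %d bonds\n",
              length(unique(x$atoms$mol)), nrow(x$atoms), nrow(x$bonds)))
  for (m in unique(x$atoms$mol)) {
    a <- x$atoms[x$atoms$mol == m, ]
    cnt <- x$system$count[match(m, x$system$mol)]
    cat(sprintf("  %s: %d atoms, mass %.3f Da, x%d\n", m, nrow(a), sum(a$mass),
                ifelse(is.na(cnt), 1L, cnt)))
  }
  invisible(x)
}

#' Identify polar hydrogens in a topology
#'
#' Polar hydrogens are atoms of mass < 2.5 Da whose name or type starts
#' with "H" and that are bonded to a nitrogen, oxygen or sulfur (judged
#' from the first letter of the neighbour's type, falling back to its
#' name). In a united-atom force field these are the only explicit
#' hydrogens. Hydrogens without any bond record are excluded with a
#' warning.
#'
#' @param top an `md_topology`.
#' @return tibble (mol, id, name, mass, heavy_id, heavy_name, heavy_mass,
#'   n_heavy); `heavy_id` is NA when the hydrogen is bonded to more than
#'   one heavy atom.
#' @export
identify_polar_hydrogens <- function(top) {
  a <- top$atoms
  is_h <- a$mass < 2.5 & (startsWith(toupper(a$name), "H") |
                            startsWith(toupper(a$type), "H"))
  res <- list()
  for (m in unique(a$mol)) {
    am <- a[a$mol == m, ]
    b <- top$bonds[top$bonds$mol == m, ]
    hs <- am[is_h[a$mol == m], ]
    if (nrow(hs) == 0) next
    for (r in seq_len(nrow(hs))) {
      h <- hs[r, ]
      nb <- c(b$aj[b$ai == h$id], b$ai[b$aj == h$id])
      if (length(nb) == 0) {
        warning(sprintf("hydrogen %s (id %d, %s) has no bond record; excluded",
                        h$name, h$id, m))
        next
      }
      nbat <- am[match(nb, am$id), ]
      elem <- toupper(substr(ifelse(nbat$type == "", nbat$name, nbat$type), 1, 1))
      heavy <- nbat[elem %in% c("N", "O", "S"), ]
      if (nrow(heavy) == 0) next
      res[[length(res) + 1]] <- tibble::tibble(
        mol = m, id = h$id, name = h$name, mass = h$mass,
        heavy_id = if (nrow(heavy) == 1) heavy$id else NA_integer_,
        heavy_name = heavy$name[1], heavy_mass = heavy$mass[1],
        n_heavy = nrow(heavy))
    }
  }
  if (length(res) == 0)
    return(tibble::tibble(mol = character(), id = integer(), name = character(),
                          mass = numeric(), heavy_id = integer(),
                          heavy_name = character(), heavy_mass = numeric(),
                          n_heavy = integer()))
  dplyr::bind_rows(res)
}

# Per-moleculetype and total system mass (Da), honouring multiplicities.
topology_mass <- function(top) {
  per_mol <- dplyr::summarise(dplyr::group_by(top$atoms, .data$mol),
                              mass = sum(.data$mass), .groups = "drop")
  per_mol$count <- top$system$count[match(per_mol$mol, top$system$mol)]
  per_mol$count[is.na(per_mol$count)] <- 1L
  list(per_mol = per_mol, total = sum(per_mol$mass * per_mol$count))
}

mass_transform_report <- function(top_before, top_after, n_modified_by_mol,
                                  method, params) {
  before <- topology_mass(top_before); after <- topology_mass(top_after)
  mols <- before$per_mol$mol
  tab <- tibble::tibble(
    mol = mols,
    count = before$per_mol$count,
    n_h_modified = unname(n_modified_by_mol[mols]),
    mass_before = before$per_mol$mass,
    mass_after = after$per_mol$mass[match(mols, after$per_mol$mol)])
  tab$n_h_modified[is.na(tab$n_h_modified)] <- 0L
  tab$gain_pct <- 100 * (tab$mass_after - tab$mass_before) / tab$mass_before
  structure(list(method = method, params = params, molecules = tab,
                 total_before = before$total, total_after = after$total),
            class = "mass_transform_report")
}

#' @export
print.mass_transform_report <- function(x, ...) {
  cat(sprintf("<mass_transform_report> %s (%s)\n", x$method,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  print(as.data.frame(x$molecules), row.names = FALSE)
  cat(sprintf("total system mass: %.4f -> %.4f Da (%+.4f)\n",
              x$total_before, x$total_after, x$total_after - x$total_before))
  invisible(x)
}

#' Hydrogen mass repartitioning
#'
#' Multiplies the mass of every selected polar hydrogen by `factor`
#' (default 4, giving 1.008 -> 4.032 Da) and subtracts the gained mass,
#' `(factor - 1) * m_H`, from the single heavy atom the hydrogen is bonded
#' to, so that each molecule's total mass — and hence the total system
#' mass — is exactly conserved. With `selection = "solute_only"` water
#' molecules are left untouched; `"solute_and_water"` also repartitions
#' water (each water hydrogen gains, the oxygen loses twice:
#' O 15.999 -> 9.951 Da for SPC).
#'
#' The transform refuses to run a second time: if the topology contains
#' hydrogen-named atoms of mass >= 2.5 Da and no remaining polar hydrogens,
#' it has evidently been repartitioned already. It also aborts, naming the
#' atom, if any heavy atom would end up non-positive or lighter than a
#' hydrogen (1.008 Da).
#'
#' @param top an `md_topology`.
#' @param selection `"solute_only"` (default) or `"solute_and_water"`.
#' @param factor mass multiplication factor for hydrogens.
#' @return list with `topology` (modified) and `report`
#'   (a `mass_transform_report`).
#' @export
apply_hmr <- function(top, selection = c("solute_only", "solute_and_water"),
                      factor = 4.0) {
  selection <- match.arg(selection)
  ph <- identify_polar_hydrogens(top)
  if (selection == "solute_only") ph <- ph[!is_water_mol(ph$mol), ]
  a <- top$atoms
  if (nrow(ph) == 0) {
    heavy_h <- a$mass >= 2.5 & startsWith(toupper(a$name), "H")
    if (any(heavy_h))
      stop("no polar hydrogens left but heavy hydrogens present: ",
           "topology appears to be repartitioned already; refusing to re-apply")
    return(list(topology = top,
                report = mass_transform_report(top, top, integer(0), "HMR",
                                               list(selection = selection,
                                                    factor = factor))))
  }
  if (any(ph$n_heavy != 1))
    stop("polar hydrogen bonded to more than one heavy atom: ",
         paste(ph$name[ph$n_heavy != 1], collapse = ", "))
  new_atoms <- a
  key <- paste(a$mol, a$id)
  for (r in seq_len(nrow(ph))) {
    hi <- match(paste(ph$mol[r], ph$id[r]), key)
    vi <- match(paste(ph$mol[r], ph$heavy_id[r]), key)
    gain <- (factor - 1) * a$mass[hi]
    new_atoms$mass[hi] <- factor * a$mass[hi]
    new_atoms$mass[vi] <- new_atoms$mass[vi] - gain
  }
  bad <- new_atoms$mass <= 0 | (new_atoms$mass < 1.008 - 1e-9)
  if (any(bad))
    stop("mass repartitioning would leave atom(s) lighter than hydrogen: ",
         paste(sprintf("%s/%s (%.3f Da)", new_atoms$mol[bad],
                       new_atoms$name[bad], new_atoms$mass[bad]), collapse = ", "))
  out <- top
  out$atoms <- new_atoms
  nmod <- table(ph$mol)
  report <- mass_transform_report(top, out, setNames(as.integer(nmod), names(nmod)),
                                  "HMR", list(selection = selection, factor = factor))
  list(topology = out, report = report)
}

#' Hydrogen isotope exchange
#'
#' Sets the mass of every selected polar hydrogen to the isotope mass —
#' deuterium 2.014, quadium 4.026, hydrogen-7 7.053 Da, or an explicit
#' numeric mass — leaving charges, type labels, bonds and heavy atoms
#' untouched. The molecule gains `n_polar_H * (m_iso - m_H)` Da. Following
#' the experimental analogy (isotope substitution of exchangeable protons),
#' the default selection leaves water alone.
#'
#' @param top an `md_topology`.
#' @param isotope `"D"`, `"Q"`, `"H7"`, or a numeric mass in Da.
#' @param selection `"solute_only"` (default) or `"solute_and_water"`.
#' @return list with `topology` and `report`, as for [apply_hmr()].
#' @export
apply_hie <- function(top, isotope = "D",
                      selection = c("solute_only", "solute_and_water")) {
  selection <- match.arg(selection)
  if (is.character(isotope)) {
    tab <- isotope_masses()
    if (!isotope %in% names(tab))
      stop("unknown isotope '", isotope, "'; valid names: ",
           paste(names(tab), collapse = ", "))
    m_iso <- unname(tab[isotope])
  } else {
    m_iso <- as.numeric(isotope)
    if (!is.finite(m_iso) || m_iso <= 0) stop("isotope mass must be positive")
  }
  ph <- identify_polar_hydrogens(top)
  if (selection == "solute_only") ph <- ph[!is_water_mol(ph$mol), ]
  out <- top
  if (nrow(ph) > 0) {
    key <- paste(top$atoms$mol, top$atoms$id)
    idx <- match(paste(ph$mol, ph$id), key)
    out$atoms$mass[idx] <- m_iso
  }
  nmod <- table(ph$mol)
  report <- mass_transform_report(top, out, setNames(as.integer(nmod), names(nmod)),
                                  "HIE", list(isotope = as.character(isotope),
                                              mass = m_iso, selection = selection))
  list(topology = out, report = report)
}

#' Write a topology, preserving everything but modified masses
#'
#' Re-emits the stored file text; for each parsed atom the mass field (the
#' eighth whitespace-separated token) is substituted with the current mass,
#' printed with four decimals and right-aligned into the original column
#' width where possible. All other lines are byte-identical to the input.
#'
#' @param top an `md_topology` with at least one atom.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  if (nrow(top$atoms) == 0) stop("refusing to write an empty topology")
  lines <- top$lines
  for (r in seq_len(nrow(top$atoms))) {
    i <- top$atoms$line[r]
    lines[i] <- replace_field(lines[i], 8, sprintf("%.4f", top$atoms$mass[r]))
  }
  writeLines(lines, path)
  invisible(path)
}

# Replace the k-th whitespace-separated token of the code part of a line
# (before any ';' comment), right-aligning into the original width.
replace_field <- function(line, k, value) {
  semi <- regexpr(";", line, fixed = TRUE)
  code <- if (semi > 0) substr(line, 1, semi - 1) else line
  tail <- if (semi > 0) substr(line, semi, nchar(line)) else ""
  pos <- gregexpr("\\S+", code)[[1]]
  len <- attr(pos, "match.length")
  if (length(pos) < k || pos[1] == -1) stop("cannot locate field ", k, " in line")
  if (nchar(value) < len[k]) value <- formatC(value, width = len[k])
  paste0(substr(code, 1, pos[k] - 1), value,
         substr(code, pos[k] + len[k], nchar(code)), tail)
}

#' Built-in demonstration topologies
#'
#' Small GROMOS-style united-atom topologies generated in code and parsed
#' through [read_topology()]'s own reader: a minimal polar H-heavy atom
#' pair, an SPC water, a cyclic (Trp)8 peptide with backbone and indole
#' N-H donors (16 polar hydrogens), and a hydrogen-free united-atom
#' lipid fragment.
#'
#' @param which one of `"polar_h"`, `"spc_water"`, `"cyclo_trp8"`,
#'   `"lipid_ua"`.
#' @param n_water multiplicity entered in `[molecules]` for
#'   `"spc_water"`.
#' @return an `md_topology`.
#' @export
demo_topology <- function(which = c("polar_h", "spc_water", "cyclo_trp8",
                                    "lipid_ua"), n_water = 1L) {
  which <- match.arg(which)
  lines <- switch(which,
    polar_h = c(
      "[ moleculetype ]",
      "; name  nrexcl",
      "MIN  2",
      "[ atoms ]",
      ";  nr  type  resnr  residu  atom  cgnr  charge  mass",
      "    1   NL      1     MIN     N      1  -0.300  12.0110",
      "    2    H      1     MIN     H      1   0.300   1.0080",
      "[ bonds ]",
      "    1    2"),
    spc_water = c(
      "[ moleculetype ]",
      "SOL  2",
      "[ atoms ]",
      ";  nr  type  resnr  residu  atom  cgnr  charge  mass",
      "    1   OW      1     SOL    OW      1  -0.820  15.9990",
      "    2   HW      1     SOL   HW1      1   0.410   1.0080",
      "    3   HW      1     SOL   HW2      1   0.410   1.0080",
      "[ settles ]",
      "    1    1   0.1 0.16330",
      "[ system ]",
      "SPC water",
      "[ molecules ]",
      sprintf("SOL  %d", n_water)),
    cyclo_trp8 = cyclo_trp8_lines(),
    lipid_ua = c(
      "[ moleculetype ]",
      "LIPF  2",
      "[ atoms ]",
      ";  nr  type  resnr  residu  atom  cgnr  charge  mass",
      "    1  CH3      1    LIPF    C1      1   0.400  15.0350",
      "    2   NL      1    LIPF     N      1  -0.500  14.0067",
      "    3  CH2      1    LIPF    C2      1   0.300  14.0270",
      "    4    P      1    LIPF     P      2   1.700  30.9738",
      "    5   OM      1    LIPF   O1      2  -0.800  15.9994",
      "    6   OM      1    LIPF   O2      2  -0.800  15.9994",
      "[ bonds ]",
      "    1    2",
      "    2    3",
      "    3    4",
      "    4    5",
      "    4    6"))
  f <- tempfile(fileext = ".itp")
  on.exit(unlink(f))
  writeLines(lines, f)
  read_topology(f)
}

# GROMOS 54a7-style united-atom cyclic (Trp)8: 16 atoms per residue, two
# polar hydrogens each (backbone amide H, indole HE1); peptide bonds close
# the ring.
cyclo_trp8_lines <- function() {
  names <- c("N", "H", "CA", "CB", "CG", "CD1", "CD2", "NE1", "HE1",
             "CE2", "CE3", "CZ2", "CZ3", "CH2", "C", "O")
  types <- c("N", "H", "CH1", "CH2", "C", "CR1", "C", "NR", "H",
             "C", "CR1", "CR1", "CR1", "CR1", "C", "O")
  masses <- c(14.0067, 1.008, 13.019, 14.027, 12.011, 13.019, 12.011,
              14.0067, 1.008, 12.011, 13.019, 13.019, 13.019, 13.019,
              12.011, 15.9994)
  charges <- c(-0.31, 0.31, 0, 0, 0, -0.1, 0, -0.1, 0.19, 0, 0, 0, 0, 0,
               0.45, -0.45)
  intra <- matrix(c(1, 2, 1, 3, 3, 4, 4, 5, 5, 6, 5, 7, 6, 8, 8, 9, 8, 10,
                    7, 10, 7, 11, 11, 13, 13, 14, 14, 12, 12, 10, 3, 15,
                    15, 16), ncol = 2, byrow = TRUE)
  atom_lines <- character(0)
  bond_lines <- character(0)
  nres <- 8L
  for (r in seq_len(nres)) {
    off <- (r - 1L) * 16L
    atom_lines <- c(atom_lines, sprintf(
      "%5d  %-4s %5d   TRP   %-4s %5d  %7.3f  %8.4f",
      off + seq_along(names), types, r, names, off + seq_along(names),
      charges, masses))
    bond_lines <- c(bond_lines, sprintf("%5d %5d", off + intra[, 1],
                                        off + intra[, 2]))
    # peptide bond C(r) - N(r+1), cyclic
    nxt <- if (r == nres) 0L else r * 16L
    bond_lines <- c(bond_lines, sprintf("%5d %5d", off + 15L, nxt + 1L))
  }
  c("[ moleculetype ]",
    "; cyclic (L-Trp-D-Trp)4, GROMOS-style united atoms",
    "CP8  2",
    "[ atoms ]",
    ";  nr  type  resnr  residu  atom  cgnr  charge  mass",
    atom_lines,
    "[ bonds ]",
    bond_lines)
}
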