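test_that("GROMOS-style topologies parse and round-trip", {
  w <- demo_topology("spc_water")
  expect_equal(nrow(w$atoms), 3)
  expect_equal(nrow(w$bonds), 2)          # implied by the settle record
  expect_true(all(w$bonds$settle))
  expect_equal(w$atoms$mass, c(15.999, 1.008, 1.008))

  f <- tempfile(fileext = ".itp")
  write_topology(w, f)
  w2 <- read_topology(f)
  expect_equal(w2$atoms$mass, w$atoms$mass)
  expect_equal(w2$atoms$charge, w$atoms$charge)

  expect_warning(topology_from_text(c("; only a comment", ";; another")),
                 "empty topology")
  expect_error(topology_from_text(c("[ atoms ]", "1 H 1 X H 1")),
               "malformed.*line 2")
})

test_that("polar-hydrogen identification is bond-based", {
  cp <- demo_topology("cyclo_trp8")
  ph <- identify_polar_hydrogens(cp)
  expect_equal(nrow(ph), 16)              # backbone H + indole HE1 per residue
  expect_setequal(unique(ph$name), c("H", "HE1"))
  expect_equal(nrow(identify_polar_hydrogens(demo_topology("lipid_ua"))), 0)
  # an all-atom C-H hydrogen is not polar
  aa <- topology_from_text(c(
    "[ moleculetype ]", "AA 2", "[ atoms ]",
    "1 CH1 1 AA CA 1 0.0 12.011",
    "2 HC  1 AA HA 1 0.0 1.008",
    "[ bonds ]", "1 2"))
  expect_equal(nrow(identify_polar_hydrogens(aa)), 0)
  # a dangling hydrogen is excluded with a warning
  dangling <- topology_from_text(c(
    "[ moleculetype ]", "DG 2", "[ atoms ]",
    "1 N  1 DG N 1 -0.3 14.0067",
    "2 H  1 DG H 1  0.3 1.008"))
  expect_warning(out <- identify_polar_hydrogens(dangling), "no bond")
  expect_equal(nrow(out), 0)
})

test_that("mass repartitioning reproduces the reference masses exactly", {
  r <- apply_hmr(demo_topology("polar_h"))
  expect_identical(r$topology$atoms$mass[r$topology$atoms$name == "H"], 4.032)
  expect_identical(r$topology$atoms$mass[r$topology$atoms$name == "N"],
                   12.011 - 3 * 1.008)   # 8.987
  rw <- apply_hmr(demo_topology("spc_water"), selection = "solute_and_water")
  expect_equal(rw$topology$atoms$mass, c(9.951, 4.032, 4.032), tolerance = 1e-12)
  # solute_only leaves water untouched
  rs <- apply_hmr(demo_topology("spc_water"), selection = "solute_only")
  expect_equal(rs$topology$atoms$mass, c(15.999, 1.008, 1.008))
  expect_equal(sum(rs$report$molecules$n_h_modified), 0)
})

test_that("mass repartitioning conserves molecular and system mass", {
  cp <- demo_topology("cyclo_trp8")
  r <- apply_hmr(cp)
  expect_equal(r$report$molecules$mass_after, r$report$molecules$mass_before,
               tolerance = 1e-9)
  expect_equal(r$report$total_after, r$report$total_before, tolerance = 1e-9)
  expect_equal(sum(r$report$molecules$n_h_modified), 16)
})

test_that("repartitioning guards against degenerate and repeated application", {
  # a heavy atom that would end lighter than hydrogen aborts with its name
  light <- topology_from_text(c(
    "[ moleculetype ]", "LT 2", "[ atoms ]",
    "1 N 1 LT NZ 1 -0.3 3.5",
    "2 H 1 LT H  1  0.3 1.008",
    "[ bonds ]", "1 2"))
  expect_error(apply_hmr(light), "NZ")
  # second application is refused
  once <- apply_hmr(demo_topology("polar_h"))$topology
  expect_error(apply_hmr(once), "refusing")
  # a molecule without hydrogens passes through unchanged
  lip <- demo_topology("lipid_ua")
  r <- apply_hmr(lip)
  expect_identical(r$topology$atoms$mass, lip$atoms$mass)
  expect_equal(sum(r$report$molecules$n_h_modified), 0)
})

test_that("isotope exchange sets exactly the tabulated masses", {
  cp <- demo_topology("cyclo_trp8")
  for (iso in c(D = 2.014, Q = 4.026, H7 = 7.053)) {
    name <- names(which(isotope_masses() == iso))
    r <- apply_hie(cp, name)
    ph <- identify_polar_hydrogens(cp)
    expect_identical(unique(r$topology$atoms$mass[ph$id]), iso)
    # heavy atoms, charges, types and bonds untouched
    expect_identical(r$topology$atoms$mass[-ph$id], cp$atoms$mass[-ph$id])
    expect_identical(r$topology$atoms$charge, cp$atoms$charge)
    expect_identical(r$topology$atoms$type, cp$atoms$type)
    expect_identical(r$topology$bonds, cp$bonds)
    # exact mass gain: n_polar_H * (m_iso - m_H)
    expect_equal(r$report$total_after - r$report$total_before,
                 16 * (iso - 1.008), tolerance = 1e-12)
  }
  expect_error(apply_hie(cp, "T"), "valid names")
})

test_that("isotope exchange through the identity isotope is an involution", {
  cp <- demo_topology("cyclo_trp8")
  d <- apply_hie(cp, "D")$topology
  back <- apply_hie(d, 1.008)$topology
  expect_equal(back$atoms, cp$atoms)
  # no polar hydrogens: unchanged, zero gain
  lip <- demo_topology("lipid_ua")
  r <- apply_hie(lip, "Q")
  expect_identical(r$topology$atoms$mass, lip$atoms$mass)
  expect_equal(r$report$molecules$gain_pct, 0)
})

test_that("writing touches only the atoms mass column", {
  cp <- demo_topology("cyclo_trp8")
  r <- apply_hie(cp, "Q")
  f <- tempfile(fileext = ".itp")
  write_topology(r$topology, f)
  out <- readLines(f)
  orig <- cp$lines
  changed <- which(out != orig)
  expect_true(all(changed %in% cp$atoms$line))
  # masses re-read match the report
  again <- read_topology(f)
  expect_equal(sum(again$atoms$mass), r$report$total_after, tolerance = 1e-9)
  # non-mass fields of changed lines intact
  expect_equal(again$atoms$charge, cp$atoms$charge)
  expect_error(write_topology(
    suppressWarnings(topology_from_text("; nothing")), tempfile()), "empty")
})

test_that("include directives are resolved when present, kept otherwise", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("[ moleculetype ]", "SOL 2", "[ atoms ]",
               "1 OW 1 SOL OW 1 -0.82 15.999",
               "2 HW 1 SOL HW1 1 0.41 1.008",
               "3 HW 1 SOL HW2 1 0.41 1.008",
               "[ settles ]", "1 1 0.1 0.16330"),
             file.path(dir, "water.itp"))
  writeLines(c("#include \"water.itp\"", "[ system ]", "w", "[ molecules ]",
               "SOL 3"), file.path(dir, "top.top"))
  top <- read_topology(file.path(dir, "top.top"))
  expect_equal(nrow(top$atoms), 3)
  expect_equal(top$system$count, 3L)
  expect_equal(scpntools:::topology_mass(top)$total, 3 * (15.999 + 2 * 1.008))
  writeLines(c("#include \"missing.itp\""), file.path(dir, "bad.top"))
  w <- capture_warnings(read_topology(file.path(dir, "bad.top")))
  expect_true(any(grepl("include not found", w)))
})
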