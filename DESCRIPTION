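Package: scpntools
Title: Geometry, Hydrogen-Bond, Solvent and Diffusion Analysis of Cyclic
    Peptide Nanotube Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing molecular-dynamics trajectories of
    transmembrane self-assembled cyclic peptide nanotubes (SCPNs): per-ring
    plane fitting and deformation observables (radial distance, angular
    deviation, out-of-plane delta angles), inter-ring centre-of-mass
    distances, tilt-angle series and their principal-component coherence,
    geometric hydrogen-bond detection with count and lifetime statistics,
    confined-water occupancy, axial patterns, positional density maps and
    slice-based pore radius profiles, and lateral diffusion coefficients
    fitted to the two-dimensional random-walk law. Includes a synthetic
    nanotube generator with known ground truth, GROMOS-style topology
    readers with hydrogen-mass-repartitioning and hydrogen-isotope-exchange
    mass transforms, and a tidy, pipe-friendly interface with ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
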