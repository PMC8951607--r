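# scpntools

Analysis of molecular-dynamics trajectories of transmembrane
self-assembled cyclic peptide nanotubes (SCPNs), for computational
chemists characterizing these channels: per-ring plane geometry and
deformation, inter-ring hydrogen-bond statistics and lifetimes, confined
water occupancy / density / pore radius, tilt coherence, and lateral
diffusion — plus a synthetic nanotube generator with recorded ground
truth and GROMOS-style topology tools for hydrogen-mass manipulation.

An SCPN is a stack of D,L-alternating cyclic peptides whose backbone
amides point along the tube axis, so each ring–ring interface forms a
β-sheet-like ladder of up to `n_residues` hydrogen bonds around a
water-filled pore. The package implements the observables used to
characterize such tubes:

* **Ring geometry.** Each ring's plane normal comes from the alternating
  cross-product estimator
  `n ∝ Σ (r'ᵢ × r'ᵢ₊₂)/|r'ᵢ × r'ᵢ₊₂|` (cyclic indexing), whose
  two-apart stencil cancels the D,L zigzag exactly. From it: radial
  distances |r''ᵢ|, signed out-of-plane δ angles, angular deviations,
  centre-of-mass distances, per-ring and whole-tube tilt, RMSD/RMSF.
* **Hydrogen bonds.** Geometric criterion (donor–acceptor ≤ 3.5 Å,
  H–donor–acceptor angle ≤ 30°), classified peptide–peptide
  (backbone-only subset), peptide–water, peptide–lipid; per-frame counts,
  per-interface breakdowns, and continuous-definition lifetimes.
* **Confined water.** Cylindrical occupancy criterion about the
  instantaneous tube axis, axial `(a-b)n` pattern classification, 2D
  positional probability maps, and a slice-based pore radius profile
  with minima at the ring planes.
* **Dynamics.** PCA of the per-ring tilt correlation matrix, and lateral
  diffusion from the 2D random-walk law
  `p(r) = r/(2Dt)·exp(−r²/4Dt)` via an exact maximum-likelihood fit with
  Gamma confidence intervals (histogram fit as cross-check); block
  averaging for error bars.
* **Topology transforms.** Hydrogen mass repartitioning (H ×4 with the
  gain taken from the bonded heavy atom; mass-conserving) and hydrogen
  isotope exchange (D 2.014, quadium 4.026, ⁷H 7.053 Da) on the polar
  hydrogens of GROMOS-style ITP/TOP topologies, with round-tripping
  writers that touch only the mass column.

Everything is tidy and pipe-friendly: analysis functions take the
trajectory first and return tibbles; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Build the idealized 8-ring × 8-residue tube with single-file channel
water, simulate 4 ns of rigid-body motion with known ground truth
(tilt signal 10°, per-ring noise 2°, lateral D = 0.001 Å²/ps, 0.1 Å
atomic jitter), and run the headline analyses:

```r
library(scpntools)

frame <- build_ideal_nanotube(nanotube_spec()) |>
  place_channel_waters("one_two")

traj <- simulate_trajectory(
  frame, motion_spec(n_frames = 2000, dt_frame = 2, tilt_common_amp = 10,
                     tilt_noise_sigma = 2, lateral_D = 0.001,
                     jitter_sigma = 0.1, seed = 42))

bonds <- hbond_series(traj)
count_summary(count_hbonds(bonds, class = "cp_cp_backbone"))
#> # A tibble: 1 x 4
#>    mean median   q25   q75
#>   <dbl>  <dbl> <dbl> <dbl>
#> 1  55.6     56    55    56

count_channel_waters(get_frame(traj, 1))
#> [1] 24
axial_pattern(get_frame(traj, 1))$label
#> [1] "(1-2)n"

glance(tilt_pca(tilt_angles(traj)))
#> # A tibble: 1 x 4
#>   n_rings n_frames matrix      first_fraction
#>     <int>    <int> <chr>                <dbl>
#> 1       8     2000 correlation           91.0

fit_diffusion(lateral_displacements(com_series(traj), window = 200))
#> <diffusion_fit> window 200 ps, n = 76 (n_eff = 19)
#>   D (MLE)      = 0.001081 A^2/ps  [0.000722, 0.001795] at 95%
#>   D (hist fit) = 0.001062 A^2/ps
```

Reading the output: the tube holds 55.6 of the 56 possible backbone
inter-ring hydrogen bonds on average (each of the 7 interfaces can form
8); the channel contains the 24 waters of the one-per-plane /
two-per-gap arrangement and is classified `(1-2)n`; 91 % of the per-ring
tilt variance loads on a single principal component, i.e. the rings tilt
as one body; and the fitted lateral diffusion coefficient brackets the
generator's true value of 0.001 Å²/ps.

Topology transforms work the same way:

```r
top <- demo_topology("cyclo_trp8")     # united-atom cyclic (Trp)8
apply_hmr(top)$report                  # H 1.008 -> 4.032, donor C/N lose 3.024
apply_hie(top, "Q")$report             # polar H -> 4.026 Da, nothing else moves
```

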