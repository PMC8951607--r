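---
title: "Methods: geometry, solvent, H-bond and diffusion analysis of cyclic peptide nanotubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, solvent, H-bond and diffusion analysis of cyclic peptide nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpntools)
```

## The system and the model

A self-assembled cyclic peptide nanotube (SCPN) is a stack of ring-shaped
peptides with alternating D- and L-amino acids. The alternation lets each
ring adopt a flat conformation in which the backbone amide N–H and C=O
groups point perpendicular to the ring plane, so consecutive rings bind
through a β-sheet-like ladder of backbone hydrogen bonds and the stack
forms a continuous transmembrane pore. For the canonical octapeptide tube
each ring–ring interface can form at most eight backbone hydrogen bonds,
and an eight-ring tube has 7 × 8 = 56 of them; the inter-ring rise and
the Cα ring radius are both close to 4.8 Å.

`scpntools` implements the trajectory observables used to characterize
these systems, together with a synthetic trajectory generator with
recorded ground truth and topology-level mass transforms. All lengths are
in Å, times in ps, angles in degrees.

## Ring geometry

For each ring the geometric centre $r_c$ is the centroid of its Cα atoms
and the plane normal is the normalized sum of normalized cross products
of centre-relative vectors two residues apart,

$$\mathbf{n} \propto \sum_i \frac{r'_i \times r'_{i+2}}{|r'_i \times r'_{i+2}|},
\qquad r'_i = r_i - r_c,$$

with cyclic indexing over all residues. The two-apart stencil is what
makes this estimator appropriate for D,L rings: the alternating ±
out-of-plane (zigzag) displacements cancel in the symmetric sum, so the
normal of an ideal zigzag ring equals that of its flat counterpart to
machine precision. The final normalization is ours — the summed vector
must be unit length for every downstream projection. The sign is fixed to
the +z hemisphere on the first frame and by continuity
($\mathbf{n}_t \cdot \mathbf{n}_{t-1} > 0$) afterwards; tilt angles are
folded to [0°, 90°], which makes all results independent of the sign
convention.

Per-residue observables derived from the plane:

* **radial distance** $|r''_i|$ of the in-plane projection from the
  centre (the ring "radius" of that residue);
* **δ angle**: the signed angle $\arcsin(r'_i\cdot\mathbf{n}/|r'_i|)$
  between $r'_i$ and the plane. On a D,L ring it alternates in sign; the
  generator builds rings so that its magnitude equals the requested
  zigzag angle exactly, which the tests recover to 10⁻⁶ degrees.
* **angular deviation** θ: the angle between $r''_i$ and the sum of the
  *unit* in-plane vectors of the remaining residues, 180° for a perfect
  polygon. A subtlety forced this design choice: because the centre is
  the centroid, the raw vectors sum to zero identically, so the
  complementary *unweighted* sum is always exactly antiparallel to
  $r''_i$ and the angle would be 180° for **any** configuration.
  Normalizing the summands breaks that cancellation and makes θ respond
  to angular distortion (an azimuthal displacement of one residue by 5°
  moves its θ by 2.5°; residues a quarter-turn away move by < 0.1°).

Whole-tube quantities: per-ring tilt (angle between the ring normal and
the membrane normal), tube tilt (from the mean of the ring normals),
mass-weighted centre-of-mass distances between consecutive rings, and
standard RMSD/RMSF with Kabsch superposition (cross-checked against
bio3d in the tests).

The plane-fit normal agrees with an SVD least-squares plane to below
0.5° on ideal fixtures carrying Gaussian positional noise up to the
fixture-stability scale of ~0.2 Å used throughout the tests; the two
estimators' mutual difference grows quadratically with noise and can
reach ~1° at the 0.3 Å jitter the trajectory generator uses for realism.
Both remain unbiased estimates of the same plane; only their agreement
band widens.

## Hydrogen bonds

A donor–hydrogen···acceptor triplet counts as a hydrogen bond when the
donor–acceptor distance is ≤ 3.5 Å and the hydrogen–donor–acceptor angle
is ≤ 30° — the convention of the standard MD analysis tools, exposed as
`hbond_criterion()`. Distances honour the minimum-image convention when a
box is present. Records are classified as peptide–peptide (with a
backbone-only flag), peptide–water, or peptide–lipid; side-chain indole
N–H donors contribute to the peptide–peptide class, which is why counts
can exceed the backbone maximum.

Lifetimes use the *continuous* definition: an instance of a given triplet
persists while present, bridging interruptions up to `gap_tolerance`
frames, and its lifetime is the spanned time. The intermittent
(autocorrelation) estimator is deliberately out of scope; literature
lifetime values computed with unstated estimators are not matched
quantitatively. For a synthetic bond that stays present with per-frame
probability $p$, instance lengths are geometric with mean
$dt/(1-p)$, which the tests verify to 10 %.

## Confined water

Water counts use a cylindrical criterion: a water oxygen is "inside" when
it lies within 4.0 Å of the instantaneous tube axis (the least-squares
line through the ring centres, oriented along the mean normal) and
axially between the terminal ring planes extended by half a ring spacing.
The 4 Å default exceeds the pore radius, so true channel waters are kept
while first-shell external waters are excluded; both parameters are
configurable. Oxygen position, not molecular centre of mass, decides
membership.

The axial occupancy pattern splits the channel into windows of half the
ring spacing centred on ring planes and on inter-ring midpoints; a
pattern is labelled `(a-b)n` when all plane-slot means round to `a` and
all gap-slot means to `b`. The idealized `one_two` arrangement — one
water per plane, two per gap — totals 8 + 14 = 22 for eight rings; the
generator adds one molecule at each channel mouth (at 3/8 of a spacing
outside the terminal planes, inside the counting bounds but outside all
classification windows), for 24 in total. The mouth convention is one
consistent reading of the idealized arrangement; it is a documented
generator choice, not a measurement.

Density maps histogram water-oxygen positions in the tube frame
(axis = z′), restricted to the six central rings, on a 0.5 Å grid,
normalized to unit total probability per map.

The pore radius profile is a deliberately simple slice method, not a
spherical-probe pathway finder: at each of 100 axial positions the inner
radius is the minimum over peptide atoms of the distance to the axis
minus the in-slice chord of the atom's van der Waals sphere
($\sqrt{r_{vdw}^2 - \Delta z^2}$). Accounting for the sphere's axial
extent keeps the profile continuous even for idealized structures whose
atoms sit at discrete heights. Absolute values are not comparable to
probe-based tools; what is reproduced is the qualitative pattern —
minima at every ring plane, maxima between planes. `profile_minima()`
merges equal-valued plateaus and discards dips of prominence below
0.15 Å, the ripple scale of individual spheres in a hard-sphere profile.

## Collective tilt and lateral diffusion

Tilt coherence is quantified by PCA of the Pearson *correlation* matrix
of the per-ring tilt series (a covariance mode exists behind a flag);
variance fractions are therefore invariant to per-series affine
rescaling. Coherent tilting loads onto a single dominant component:
with per-ring noise at one fifth of the common signal the first
component carries > 90 % of the variance.

Lateral diffusion is estimated from the magnitudes of in-plane
centre-of-mass displacements over a time window $t$. For an isotropic 2D
Brownian walk these follow the Rayleigh-form law

$$p(r) = \frac{r}{2Dt}\, e^{-r^2/4Dt},$$

and the maximum-likelihood estimator is $\hat D = \sum r_k^2 / (4 t n)$,
with an exact Gamma-distribution confidence interval. Windows are drawn
with a default stride of a quarter window; the resulting dependence is
acknowledged through an effective sample size $n\,\mathrm{stride}/t$ in
the interval (with non-overlapping windows the interval is exact). A
histogram least-squares fit of the same law is reported alongside as a
cross-check, since published distribution-fit analyses typically work on
binned curves. Parameter recovery is validated in the tests over three
decades of $D$ (10⁻³–10⁻¹ Å²/ps) through the package's own generator:
200 replicate walks at $D = 0.01$ Å²/ps give relative bias below 2 % and
95 % interval coverage within [90 %, 98 %].

Uncertainties of time-averaged observables use block averaging: the
series is cut into 5 contiguous blocks by default and the standard error
of the mean is the scatter of block means over $\sqrt{n_{blocks}}$;
1.96 × SE is exposed for 95 % error bars. For positively autocorrelated
series this exceeds the naive i.i.d. error, as it should.

## The synthetic generator and what it does (not) emulate

`build_ideal_nanotube()` constructs the idealized 8 × 8 tube: Cα rings of
radius 4.8 Å stacked every 4.8 Å, each Cα at its full radius with an
out-of-plane angle equal to the zigzag angle (default 1.4°, the value
characteristic of united-atom parameterizations; 2.8° reproduces the
scale seen with all-atom ones). Backbone amide units are aligned with
the tube axis, alternating direction residue-to-residue identically in
every ring, so that at each interface every column pairs one donor with
one acceptor — the antiparallel registry — and exactly eight backbone
bonds form per interface. The amide N and C sit 0.335 Å off the ring
plane along the amide axis with N–H = 1.0 Å and C=O = 1.23 Å, giving an
interface N···O distance of 2.90 Å (β-sheet-like) and a collinear
H···O geometry, comfortably inside the default criterion.

`simulate_trajectory()` superimposes three motions with recorded ground
truth: (1) a whole-tube tilt about a fixed membrane-plane axis following
an AR(1)-smoothed Gaussian signal (coefficient 0.99 per frame, so the
tilt evolves progressively rather than jumping; stationary sd =
`tilt_common_amp`), plus independent per-ring Gaussian tilt noise
applied about the same axis so that the true per-ring tilt is exactly
the sum; (2) a 2D Brownian walk of the tube centre with
$\langle\Delta x^2+\Delta y^2\rangle = 4D\,dt$ per step (default
10⁻³ Å²/ps = 1 Å²/ns, typical of a transmembrane assembly); (3) i.i.d.
Gaussian jitter on every atom (default 0.3 Å). Defaults of 1000 frames
at 2 ps spacing keep analyses at desk scale; the acceptance analyses use
5000 frames for the tilt PCA and ~2000-frame walks for diffusion
recovery.

Two measurement-side consequences are worth stating. First, because the
common tilt signal is zero-mean while measured tilts are folded to
[0°, 90°], the folding attenuates the common signal (a zero-mean
Gaussian of sd 10° has half-normal sd ≈ 6°), so with 2° ring noise the
expected first-PC fraction sits near 90–92 % rather than the ~96 % an
unfolded signal would give, and single-run estimates fluctuate by a few
points because the AR(1) correlation time (~100 frames) leaves few
independent samples. Second, the generator is rigid-body plus white
noise: it has no internal ring deformation modes, no water–water
structure, no lipid chains and no force field, so passing tests
demonstrate correctness of the estimators on known ground truth — not
realism of any particular simulated ensemble.

What the generator does **not** emulate: thermal breathing of the rings,
correlated (non-white) atomic fluctuations, water exchange with the
bulk, membrane undulations, and any energetics. Observables whose
realistic values depend on those — absolute H-bond lifetimes, water
counts under thermal disorder, per-force-field differences — are outside
what synthetic trajectories can validate.

## Topology mass transforms

The GROMOS-dialect reader parses `[moleculetype]`, `[atoms]`, `[bonds]`,
`[settles]` and `[molecules]` sections, preserves everything else
verbatim, and resolves `#include` when the file is present (otherwise the
line is kept and the block skipped, with a warning). Polar hydrogens are
identified by bonding — mass < 2.5 Da, name/type starting with H, bonded
to N, O or S — rather than by name alone, for robustness across
dialects; a settle record implies the two O–H bonds of a rigid water.

Two transforms operate on the polar hydrogens:

* **Hydrogen mass repartitioning** (`apply_hmr()`): each hydrogen's mass
  is multiplied by a factor (default 4: 1.008 → 4.032 Da) and the gained
  mass is taken from its single bonded heavy atom (12.011 → 8.987 Da for
  a carbon donor; SPC oxygen 15.999 → 9.951 Da when water is included).
  The multiply-by-factor convention reproduces the reference masses of
  the automated GROMACS implementation exactly, which a plain "transfer
  3 Da" would not (3.024 Da moves per hydrogen). Per-molecule and total
  mass are conserved to 10⁻⁹ Da; the transform refuses to run twice and
  aborts if a heavy atom would end lighter than hydrogen.
* **Hydrogen isotope exchange** (`apply_hie()`): masses are set directly
  to deuterium (2.014), quadium (4.026), hydrogen-7 (7.053), or an
  explicit value, with charges, types and bonds untouched. Water is
  excluded by default, matching the convention that only the solute's
  exchangeable protons are substituted. Exchanging back through mass
  1.008 restores the original topology exactly.

Both return a report with per-molecule masses before/after and gain
percentages. For a united-atom cyclic (Trp)₈ with its 16 polar
hydrogens the computed gains are ≈ 1.1 % (D), 3.2 % (Q) and 6.5 % (H7)
of the molecule's ~1490 Da; the report always prints the computed
fractions rather than any externally quoted ones, whose basis we could
not reproduce from the atom masses.

## Numerical choices and degenerate inputs

* Angles from `acos` lose ~10⁻⁶ degrees of precision near 0°/180°;
  equality tests on θ use 10⁻⁵.
* `ring_normal()` errors on collinear inputs (cross products below
  10⁻¹²); `tilt_pca()` drops constant series with a warning and requires
  ≥ 10 frames per ring; `fit_diffusion()` flags all-zero displacement
  sets as degenerate; empty slices in the radius profile are masked, and
  `run_pipeline()` records an NA first-PC fraction for motionless
  trajectories instead of failing.
* I/O: PDB (single and multi-model) goes through bio3d; GRO is written
  in the fixed-width GROMACS format (0.001 nm precision). Compressed
  binary trajectory formats are not supported; long trajectories
  round-trip through multi-model PDB.
* Ring membership defaults to residue-index blocks of `n_residues`
  (or PDB chains), matching the positional ring numbering of stacked
  tubes.
* The equilibration discard is exposed as a `discard` time on every
  trajectory-level function (default 0 for synthetic data, where there
  is no equilibration to discard).

## Known limitations

The radius profile is not a pathway finder and its absolute values
should not be compared with probe-based tools. The angular deviation θ
uses the unit-vector complementary sum for the reason given above; its
absolute scale is therefore half of the naive per-residue azimuthal
displacement. H-bond lifetime values depend on the continuous-definition
choice and the frame spacing; only relative comparisons are meaningful.
The histogram diffusion fit depends mildly on binning and is reported
only as a cross-check on the MLE.
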