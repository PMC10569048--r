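---
title: "Methods: ion atmospheres, entropy and free-energy surfaces for parallel DNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion atmospheres, entropy and free-energy surfaces for parallel DNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixatmos)
```

## The problem

Like-charged DNA duplexes attract each other in the presence of multivalent
cations. The attraction is tiny per base pair (on the order of 0.1 kJ/mol/bp)
but additive along the helix, so it drives condensation of long DNA. Resolving
the mechanism requires several kinds of analysis applied to simulations of two
parallel duplexes: where the cations sit (the ion atmosphere), how much charge
is condensed in successive surface shells, how the hydration structure
changes, how much entropy the ions, water and DNA gain or lose between the
free state (axis separation d = 4.0 nm) and the condensed state
(d = 2.8 nm), and the potential of mean force over the two collective
variables of the pair geometry — the interhelical distance d and the
azimuthal rotation theta of the mobile helix about its own axis.

`helixatmos` implements this analysis machinery as a tested R package. It
does not run molecular dynamics; every estimator is exercised against
synthetic configurations with known ground truth, which is what the test
suite and `scripts/acceptance.R` verify. The functions are the interface:
each stage takes data frames or light S3 containers and returns tibbles, so
stages compose with the pipe.

## Internal conventions

All coordinates are in angstrom, times in ps, masses in amu, charges in
units of the elementary charge, energies in kJ/mol; the interhelical
distance d is quoted in nm, matching the scale on which the states are
defined. The helix long axis is +z; theta is measured counterclockwise in
the xy-plane and wrapped to [0, 2 pi). Boxes are orthorhombic and distances
are minimum-image in all three dimensions. `ha_constants()` exposes the
constants used (Coulomb constant 1389.35 kJ mol^-1 A e^-2, kT at 300 K =
2.494 kJ/mol).

## Synthetic ground truth

The generator module defines the study conditions.

* **Duplex pairs** (`build_duplex_pair()`): a reduced B-form model — one
  phosphate pseudo-atom per strand per base pair (charge -1 e) on a cylinder
  of radius 8.9 A, with rise 3.4 A/bp and twist 36 deg/bp, the two strands
  offset by a groove phase of 154 deg so the major and minor grooves have
  B-DNA-like unequal widths; groove-marker pseudo-atoms sit on the groove
  bisectors. All-atom detail is deliberately absent: the analysis math
  (densities, shells, Coulomb sums, order parameters) only needs labeled
  sites with charges and masses. The default box is 11.8 x 11.8 x 6.8 nm
  with the pair centered, and 20 bp span the 6.8-nm z-extent exactly twice
  per helical repeat, so z-periodic continuation is consistent.
* **Ion placements** (`place_ions()`): `uniform_bulk` draws a
  Poisson(c V N_A) count with uniform positions outside a hard core —
  the ideal-gas reference every density estimator must reproduce;
  `helical_groove_chain` places ions at Gaussian displacements from helical
  guide curves offset 3 A radially from the backbone, emulating the
  continuous chains of condensed-cation density that form along the grooves.
  The generating distribution is recorded so tests can compare against it.
* **Velocities** (`sample_velocities()`): Maxwell-Boltzmann components at a
  set temperature with the center-of-mass momentum removed.
* **Toy sampler** (`run_langevin_wtmd()`): overdamped Langevin dynamics on
  an analytic 2D potential with well-tempered hill deposition
  (`h = h0 exp(-V_bias / (kB T (gamma - 1)))`). The default double well has
  basins at d = 2.8 and 4.0 nm, a 6 kJ/mol barrier, a 3 kJ/mol depth
  asymmetry favoring the condensed basin, and a weak periodic theta well —
  enough structure to stress the reconstruction without hiding it in noise.

What the generator does *not* emulate: sequence-specific base geometry,
force-field energetics, water-mediated correlations, or the slow collective
dynamics of a real ion atmosphere. Passing tests therefore demonstrate that
the estimators are correct, not that any particular simulation is converged.

## Ion atmosphere

`number_density()` histograms wrapped positions on a 1-A voxel grid (the
spacing is adjusted, at most 5%, so the grid tiles the box exactly) and
divides by frames times voxel volume; the field integral equals the mean
particle count by construction, which the tests assert to 1e-6.
`cylindrical_concentration()` converts to concentration in mol/L around the
helix axis in 0.5-A shells, normalizing by the exact shell volume
pi (lambda_out^2 - lambda_in^2) L. The axis is a per-frame least-squares
line through the restrained helix's phosphates — the frame-wise fit
tolerates helix drift. `excess_ions()` integrates c(lambda) - c_bulk over
shells; when no bulk value is supplied it is estimated from the outermost
20% of bins, a choice that matters only when the profile has not reached
bulk within the analysis cylinder.

Shell charges (`excess_charge_by_shell()`) use the distance to the nearest
DNA atom, not to the axis, with the study's three shells: R1 = 3.5 A
(hydration), R2 = 6 A (tight cation binding), R3 = 10 A (Debye layer). The
RDF uses exact spherical shell volumes; the surface distribution function
(SDF) bins distance-to-nearest-reference-atom and normalizes by
Monte-Carlo-estimated accessible shell volumes (seeded, 1e6 points by
default) because no closed form exists for shells around an irregular
surface; a bin whose volume estimate has more than 25% relative error
raises a resolution error instead of returning a silently noisy value.

## Shell electrostatics

The stored interhelical energy U_d is defined as the cross Coulomb energy
between two charge groups, each consisting of one helix plus the mobile
charges within a 10-A surface shell assigned to it (nearest-helix
assignment; exact ties are excluded and logged). This is the reading of
"energy stored between the helices" that makes U_d a function of d alone
and lets Newton's-third-law symmetry serve as an internal check (asserted to
1e-9 relative). The Coulomb sum is direct, in vacuum by default with a
configurable relative permittivity, and deliberately non-periodic: the shell
restriction embodies the Debye-screened real-space picture, and image
contributions beyond the primary cell are excluded by construction. Energies
along the path are reported as changes relative to the largest-d bin.
`energy_vs_distance()` is validated against the closed-form parallel
line-charge integral (and independent numerical quadrature) at 1%.

## Hydration structure

The tetrahedral order parameter per water is
`S_g = (3/32) sum_(j<k) (cos psi_jk + 1/3)^2` over the four nearest water
oxygens (minimum image). The 3/32 factor bounds S_g in [0, 1]; a perfect
tetrahedron gives 0, and isotropic random neighbors give 1/4 in expectation
(both asserted). Neighbors are the four nearest oxygens regardless of
distance, with a 5-A cutoff that only triggers the skip rule for
under-coordinated waters; per-water values are averaged in 0.5-A
cylindrical shells. The profile reports mean S_g (tetrahedrality increases
as S_g decreases); whether a bound-water boundary is drawn at an S_g level
or at its gradient is left to the user since the underlying convention is
ambiguous in the field.

Hydrogen bonds use the geometric criterion: donor-acceptor distance at most
3.5 A and donor-H...acceptor angle at least 150 degrees. No universal
criterion exists; both thresholds are arguments. Counting is restricted to
waters whose oxygen lies within R1 of the DNA surface, with water-water and
water-phosphate bonds included. Missing hydrogens raise a capability error
rather than silently switching criteria.

## Entropy

Solvent entropy uses two-phase thermodynamics (2PT). The density of states
is the cosine transform of the mass-weighted velocity autocorrelation,
normalized so its one-sided integral equals the number of degrees of
freedom; the VACF is computed by FFT with zero padding and truncated at
min(10 ps, half the window) by default — no taper is applied, so fixtures
are designed with the correlation window an integer number of periods where
spectral purity matters. The zero-frequency value s0 fixes the normalized
diffusivity Delta and the fluidicity f through the standard self-consistency
polynomial, solved by bracketed root finding to 1e-10. The gas-like
component `s0 / (1 + (pi s0 nu / 6 f N)^2)` carries exactly 3Nf degrees of
freedom and is scored with the hard-sphere entropy (Sackur-Tetrode at the
gas-component density with the Carnahan-Starling compressibility inside the
logarithm and the CS excess term — the convention of the canonical 2PT
implementations); the solid-like remainder is scored with the quantum
harmonic oscillator weighting. Near the solid limit the nominal packing
fraction can exceed close packing where the CS form is meaningless; since
the gas component is then negligible it is dropped, and a non-negligible
gas component beyond close packing is an error. Water uses the
rigid-molecule decomposition (center-of-mass translation plus angular
velocity about instantaneous principal axes; the vibrational remainder is
scored as pure solid); ions are translation-only.

DNA conformational entropy uses the whole-molecule quasi-harmonic terms:
the covariance of the center of mass and of the orientation (rotation-vector
displacement from a reference frame, projected on the principal axes of
inertia) define effective harmonic frequencies
`nu = (1/2 pi) sqrt(kT / (M lambda))`, each scored as a QHO mode. The
topographical term of the full multiscale decomposition is omitted — for a
well-defined double helix its change between states is negligible — and the
multiscale cell hierarchy is out of scope; this is a deliberate
simplification, validated against an analytic isotropic tether at 2%.

`entropy_change_report()` assembles -T dS for cations, DNA and water between
the condensed and free states with block-averaged uncertainties (5 equal
blocks by default; the uncertainty is the standard error over blocks).

## Free-energy surfaces

`reconstruct_fes()` sums the deposited Gaussians (theta through wrapped
angular differences, so every periodic image within the wrap is exact) and
applies `F = -(gamma/(gamma-1)) V_bias`, shifted to min 0. The default grid
is 0.02 nm by 2 degrees. Because the instantaneous well-tempered bias
oscillates around the converged profile, the optional `average_from`
argument reconstructs from the bias time-averaged over the later deposition
checkpoints — the standard time-averaged estimator; the plain sum remains
the default. Projection to F(d) is a Boltzmann-weighted marginalization
over theta via a log-sum-exp. Minima are grid-local minima with
theta-periodic neighborhoods, refined by independent quadratic fits along
each axis, and filtered by a prominence threshold (default 0.5 kJ/mol)
against the barrier toward the global minimum. `delta_f()` interpolates
linearly — the profiles are smooth at the default grid, and higher-order
interpolation invites overshoot at well edges — and scales per base pair
(the worked example: -0.15 kJ/mol/bp gives 45 and 75 kJ/mol of
stabilization for 300- and 500-bp pairs).

Convergence is diagnosed two ways (`convergence_diagnostics()`): the decay
of hill heights toward an asymptote (flag: final-block mean below 20% of the
first block's by default), and a block analysis in which each block's
surface is reconstructed from that window's deposition alone — once a
tempered run has converged, deposition is uniform over the visited region,
so per-block bound/free differences collapse toward zero and their spread
measures residual sampling error.

### Validation harness and problem sizes

`fes_recovery_benchmark()` fixes the toy-study conditions: 4e6 overdamped
steps (dt 0.01 ps, friction 50 kJ mol^-1 ps nm^-2), hills every 200 steps
with h0 = 0.8 kJ/mol, widths (0.08 nm, 0.6 rad), gamma = 8, reconstruction
time-averaged over the last 70% of hills. At these settings the projected
profile recovers the analytic marginal within ~0.3 kJ/mol (5% of the
barrier) across seeds, against an acceptance tolerance of 10% of the
barrier; the run takes on the order of a minute. The regular test suite
uses a 3e5-step scaled-down run with correspondingly coarser bounds; the
2PT fixtures use 16384 frames (N = 500 particles for the gas), and the
Boltzmann-sampling check uses 1e5 plain Langevin steps thinned to 2000
samples with a Kolmogorov-Smirnov threshold of 0.05.

## Condensation-path pipeline

`path_spec()` fixes the study's path: 0.5-A bins in d, condensed state at
2.8 nm, free state at 4.0 nm, a 500-snapshot budget.
`bin_frames_by_distance()` recomputes d per frame from the fitted axes and
assigns frames by raw binning (no bias reweighting — snapshots are taken as
given, and the choice is recorded here because reweighting is a valid
alternative). `condensation_profile()` reports bound waters (R1), hydrogen
bonds (R1), cation coordination (R3 change and absolute R2 count) and the
stored-energy change, each relative to the largest-d occupied bin, matching
the "change relative to the free state" convention of the analysis this
package implements. `full_report()` runs the whole synthetic study and
writes TSV tables, the HILLS file, the free-energy tables, an entropy
report, and a JSON provenance manifest (package version, seed, config
hash); stage failures are isolated and enumerated rather than aborting the
bundle.

## Known limitations

* The reduced duplex representation carries no sequence information beyond
  configurable charge-site patterns; nothing here distinguishes AT-rich from
  mixed-sequence DNA except through the user's own inputs.
* The Coulomb stage has no Ewald summation; it is not suitable for systems
  where long-range periodic electrostatics matter beyond the shell picture
  it implements.
* 2PT entropies inherit the method's known biases (the hard-sphere mapping
  of the diffusive component); the MCC-style DNA term implements only the
  single-molecule translational and rotational vibrations.
* The HILLS reader accepts the whitespace/`#!`-header dialect only; binary
  trajectory formats (XTC/DCD) are out of scope.
* Exports are plain text (TSV, OpenDX, PDB/GRO/XYZ, JSON); no HDF5 backend
  is provided.
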