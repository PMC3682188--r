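---
title: "Coarse-grained modeling of ENTH membrane binding and self-association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modeling of ENTH membrane binding and self-association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(enthcg)
```

`enthcg` models how epsin N-terminal homology (ENTH) domains bind curved
membranes and self-organize into ordered coats, together with the CW-EPR
analysis chain used to constrain that organization experimentally.  This
vignette is the package's account of the models it implements, the
parameters that matter, and the choices made where the design was open.

## The membrane model

Each lipid is a single anisotropic particle: a Gay-Berne ellipsoid with a
3:1 aspect ratio (length/breadth sigma0) carrying a head-to-tail director.
The standard Gay-Berne orientation-dependent contact length and well depth
are used with exponents mu = 2, nu = 2 and well anisotropy kappa' = 5, and
the interaction is smoothly truncated (quintic switch) in the *reduced*
separation rho = (r - sigma + sigma0)/sigma0, so the real-space cutoff
follows the pair's orientation.  Amphiphilicity - the broken symmetry along
the long axis - enters as an additional term `eps_hb (u_i - u_j) . r_hat
rho^-6`, odd under flipping a single director, which favors tail-tail over
head-head apposition and selects the bilayer arrangement.

The in-plane lipid-lipid force field of the original hybrid analytical-
systematic (HAS) lipid was parameterized from atomistic data that is not
published; the package substitutes this calibrated fixture set:

* `sigma0 = 0.77` nm, chosen so the side-by-side pair minimum (0.86 nm)
  matches the fixture area per lipid of 0.75 nm^2 - the value that also
  reproduces the reference systems' lipid counts (a 16 nm x 50 nm tube
  takes ~6.7k lipids; a 50-nm vesicle ~21k).
* `epsilon0 = 0.95` kcal/mol with nu = 2, giving a side-by-side well of
  2.6 kcal/mol (~4.4 kT at 300 K).  With weaker orientational coupling
  (nu = 1) the director field disorders and the bilayer evaporates at
  300 K; the chosen values keep a tensionless flat bilayer intact over
  at least 1e5 steps, which is the calibration criterion.
* Leaflet center planes sit at half the end-to-end pair minimum, so
  opposed leaflets rest at their tail-tail equilibrium.

Units are nm, ps, kcal/mol and K throughout; EPR-side observables are
reported in Angstrom and Gauss.  CG masses are set to 1 (lipids and
protein sites) with a lipid moment of inertia of 0.4, appropriate for a
3:1 ellipsoid of unit mass; CG dynamics has no direct mapping to atomistic
time in any case.

## The 16-site ENTH domain

The domain is 16 CG sites: two H0 amphipathic-helix sites (sites 1 and 2,
whose connecting vector defines the H0 axis), the V50/V51 hydrophobic
patch (site 5), the R114 loop (site 10), a PIP2-binding pocket
(configurable, default site 7) and a generic body.  Site placement on a
real trajectory is the job of `edcg_partition()`: an exact dynamic program
over contiguous segment boundaries minimizing the essential-subspace
fluctuation variance lost by center-of-geometry mapping (ties break toward
the earlier boundary; the essential subspace defaults to the smallest PCA
set capturing 90% of variance).  Internal springs come from
`heteroenm_fit()`, damped fluctuation matching
`k_ij <- k_ij (var_model/var_target)^0.5` against pair-distance variances,
with the model variances computed from the ENM Hessian pseudoinverse.

The packaged reference coordinates are an idealized, synthetic stand-in
(the residue-to-site assignment for ENTH is not published): H0 sites on
the membrane plane at the dimer-interface side, a compact body leaning
away from the interface, and nitroxide label anchors for residues 4, 5, 6,
10, 13 and 14 placed 5-9 Angstrom off their owning H0 site at helix-like
axial spacing.  The anchor geometry was designed once so that a rigid
two-fold-symmetric placement can satisfy all measured interlabel distances
simultaneously; the dimer/tetramer builders then *fit* that placement by
least squares and verify it with an independent distance routine.  The
default internal springs are homogeneous at 500 kcal/(mol nm^2): bond
fluctuations then stay below 0.04 nm so the H0 axis direction reflects
domain orientation rather than internal floppiness (protein-scale
stiffness, as fluctuation matching against a real trajectory would give).

## The interaction table

Five attractive channels ride on top of generic excluded volume:

| channel | depth (kcal/mol) | reading |
|---|---|---|
| H0 sites - membrane | 4 total (2 per site) | adhesion depth of the site against a flat leaflet; converted to a per-pair epsilon by `calibrate_site_membrane_eps()` |
| R114 loop - lipid | 1.2 | per-pair (the value originates from a site-lipid pair PMF) |
| PIP2 pocket - PIP2 lipid | 2.4 | per-pair; only the 10% PIP2-flagged lipids |
| H0 site 1 - H0 site 2, different domains | 2 | per-pair; the end-to-end lattice contact |
| patch - patch (site 5) | 2 | per-pair; the dimer-dimer hydrophobic contact |

Two deliberate departures from a naive reading deserve a note.  First, the
inter-domain H0 interaction acts specifically between site 1 and site 2 of
different domains, not between all H0 sites: with the generic version,
parallel side-by-side H0 stacking collects roughly -6 kcal/mol and
outcompetes the EPR-derived lattice, which then collapses into disordered
aggregates.  Second, all remaining cross-domain site pairs carry a weak
generic Lennard-Jones well (0.2 kcal/mol) rather than pure WCA repulsion:
protein-protein interactions in this model class are LJ throughout, tuned
so that domains cohere without condensing.  To cap the coordination number
of the attractive channels - which a 16-site idealized body is too slim to
do on its own - the simulator adds one internal excluded-volume "core"
particle per domain (WCA, core-core contact 1.55 nm, pinned to the body by
stiff springs).  The core is bookkeeping inside the integrator, not a
topology site; without it, pairwise additivity drives condensation into
aggregates denser than the designed lattice.

## Dynamics

`run_nvt()` integrates positions with velocity Verlet and directors by
torque integration of a linear rotor (angular velocity kept perpendicular
to the director, renormalization each step), coupled to a single
Nose-Hoover chain (tau = 0.1 ps, Q = g kT tau^2) at 300 K with dt =
0.001 ps.  Forces are analytic throughout, including the Gay-Berne
orientation gradients, and are verified against finite differences to
1e-5; with the thermostat off the integrator conserves energy to better
than 0.02% over 1e4 steps and momentum to machine precision.  Neighbors
come from a Verlet list (0.3 nm skin, rebuilt on half-skin displacement)
built with a periodic-aware cell grid.  A per-step energy-divergence guard
aborts with a diagnostic frame.  An optional warmup argument ramps the
time step and temperature in stages, mirroring the gradual heat-up used
for this model class; the packaged protocols start production directly,
which proved gentler for the prearranged coats than a long low-temperature
ramp (a cold Gay-Berne membrane stiffens and cracks).

## EPR-restrained construction

`build_h0_dimer()` places two copies of the domain related by a two-fold
axis perpendicular to the membrane plane and fits the monomer pose (two
in-plane translations, in-plane rotation, roll about the H0 axis) to the
intra-dimer interlabel restraints (residues 6 and 10 at 13 A, residue 5 at
9 A, residue 4 broad at 21 A) with a soft clash and membrane-side penalty.
`build_tetramer()` adds a second dimer by an axial-plus-lateral offset fit
to the inter-dimer restraints (residue 13 at 15 A, residue 14 at 10 A)
with the site-5 patches required to touch.  Construction quality is always
re-measured by `measure_anchor_distance()`, a standalone routine that knows
nothing about the fit.

`coat_tube()` tiles the tubule coat from helical strands of dimers, each
strand repeating the fitted tetramer offset so every consecutive pair
shares the patch and end-on H0 contacts.  Strand count defaults to the
circumference divided by the dimer footprint (3.85 nm), giving a laterally
contiguous coat; on a periodic tube whose length is a whole number of
rises the helical drift is nudged by a fraction of an Angstrom so the
helix closes seamlessly across the boundary (no strand ends).  Cap
coverage on capped tubes places dimers on the hemispheres with axes along
the local meridian.  `scatter_vesicle()` and `dimer_scatter_vesicle()`
place monomers/dimers at seeded random surface points, H0 sites 0.5 nm off
the outer headgroup shell.

## Order analysis

`local_order()` implements the coat order parameter: for each domain the
unsigned dot product of H0 axes averaged over neighbors within 5 nm
(self excluded - including self would bias every S_i upward uniformly),
with isolated domains carried as NA.  Cell-list and brute-force neighbor
searches are interchangeable and tested to give identical results.
`order_trace()` tracks the global mean over snapshots and calls the run
converged when the trailing 25% shows no Mann-Kendall trend at the 5%
level.  `segment_order()` reports per-segment means under two offset
segmentation choices, `find_defects()` flags domains below a configurable
threshold (default 0.8, separating the ordered and disordered extremes of
the coat's color maps), and `insertion_depth_profile()` measures signed H0
depths below the headgroup shell fitted as a plane, cylinder or sphere
(positive = inserted).

## EPR analysis chain

Accessibility contrast is `Phi = ln(Pi_O2/Pi_NiEDDA)`; depth conversion is
the linear calibration `d = a Phi + b` fit by ordinary least squares
(`calibrate_depth()`; the reference constants are a = 3.5, b = 0.37).
`fit_periodicity()` profiles the cosine period on [3, 5] residues with the
amplitude/phase/offset solved linearly at each period, then polishes by
golden-section search - an ideal amphipathic helix returns 3.60;
`helical_wheel()` assigns lipid- and solvent-facing faces from the fitted
phase.  `estimate_distance()` fits a spin-dilution pair: the full-labeled
spectrum is modeled as the diluted spectrum mixed with a dipolar-broadened
copy, parameterized by interacting fraction, distance and distributional
width, after both spectra are normalized to the same number of spins by
double integration (with linear baseline removal).  The broadening kernel
is Gaussian in field with sigma_B = C / r^3, C = 6.6e3 G A^3 (sigma_B at
13 A comparable to the intrinsic linewidth), mixed over a Gaussian
distance distribution truncated at the 5 A sensitivity floor.  The
optimizer is bounded nonlinear least squares with five distance starts
spanning the 5-25 A sensitivity range.  Intrinsic lineshape constants
(three Lorentzian-derivative lines, 15 G hyperfine, 2.2 G width) are
representative values; all distance-recovery statements are
generator-estimator self-consistent, which is exactly what they are tested
as.

## Interfacial partitioning

`interfacial_dg()` sums Wimley-White water-to-POPC-interface residue
values (Arg/Lys charged, His neutral) plus end-group adjustments, and adds
a folding contribution `helicity x n x folding_bonus`.  The published
per-residue folding bonus of -0.4 kcal/mol is kept, and the helical count
defaults to the full sequence length: for the 15-residue H0 this makes the
slope in helicity 6.0 kcal/mol, which is the only count consistent with
the reference endpoints (-3.4 kcal/mol at 85% helicity, -4.3 at 100%)
under the published bonus.  The end-group constants for the NH3+/CONH2
termini (-0.45 and -0.90 kcal/mol) were calibrated once so the
full-helicity H0 computation lands on -4.3 kcal/mol given the residue sum
(+3.05 kcal/mol for MSTSSLRRQMKNIVH); they are configurable.  Helicity is
applied as a uniform fraction (the alternative - removing terminal
residues from the helix - would make the sweep only piecewise affine).

## Synthetic data

Every estimator input can be generated with known ground truth:
`gen_enm_trajectory()` draws i.i.d. frames from the exact Gaussian
ensemble kB T H^+ of an elastic network (all zero modes - the six
rigid-body ones plus any floppy modes of degenerate geometries - projected
out), `gen_pair_spectrum()` produces matched spin-dilution pairs,
`gen_accessibility_profile()` cosine accessibility profiles, and
`gen_calibration_points()` linear depth-calibration sets.  All are pure
functions of their arguments plus one explicit seed (bitwise
reproducible); global RNG state is saved and restored.

What the generators do *not* emulate: multi-component lineshape
heterogeneity and rotational-mobility effects in room-temperature spectra,
anharmonic protein dynamics beyond the Gaussian network, and spectrometer
baseline artifacts beyond a linear term.  Passing recovery tests therefore
demonstrates correctness of the estimators under the stated models, not
robustness to every feature of measured spectra.

## Desk-scale protocols and what they show

The packaged simulation protocols are deliberately small so that the whole
pipeline reruns in minutes on one CPU; all sizes are package choices:

* Periodic (type A analog) tube: 16-nm diameter, length 7 lattice rises
  (11.5 nm, seamless coat closure, 224 domains over ~1.5k lipids), 14,000
  production steps per seed, 3 seeds, order averaged over the converged
  trailing quarter.  This reproduces the ordered-coat regime
  quantitatively (converged order near 0.9 against the full-scale
  reference of 0.92) and the control contrast (removing the H0-H0
  attraction drops the converged order to ~0.55-0.6 under matched seeds).
* Capped (type B analog) tube: 12-nm cylinder plus hemispherical caps,
  ~250 domains, 9,000 steps.  At this scale the caps hold ~18% of the
  domains versus roughly half that in the full-length system, so the
  cap disorder the analysis is designed to expose weighs more heavily on
  the global mean, which lands below the full-scale reference value
  (~0.75-0.8 versus 0.88); the middle-versus-cap contrast itself is
  qualitatively preserved and visible through `segment_order()`.
* Vesicle: 16-nm diameter with 45 scattered monomers (the coverage of 441
  domains on a 50-nm vesicle), 8,000 steps; scattered monomers relax to
  local order ~0.5, far below any tube coat.

Known limitations: the fixture domain geometry is an idealized stand-in
rather than an EDCG mapping of the crystal structure; the membrane model
is a generic Gay-Berne parameterization rather than the original
atomistically-matched in-plane force field; wedge-curvature coupling of
the inserted helix is not representable with isotropic site-lipid
potentials, so tubule alignment relies on the lattice contacts; and CG
time has no atomistic mapping, so step counts are compared only through
converged averages.
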